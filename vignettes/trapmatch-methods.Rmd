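---
title: "Detecting and classifying mosquitoes in trap images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying mosquitoes in trap images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trapmatch)
```

## The problem

Optical suction traps photograph insects as they pass a fixed-distance
imaging channel in front of a dark cloth background, lit from above. Because
the capture distance is fixed, the apparent size of an insect barely varies,
which makes two classical techniques viable: template matching for
*detection* (is there an insect, and where?) and contour shape features for
*classification* (is it a mosquito or some other insect, e.g. a bee?).
trapmatch implements that pipeline: grayscale conversion, border padding,
normalized cross-correlation matching with iterative peak covering, ROI
shape analysis, and recall/precision/F-measure evaluation, plus a seeded
synthetic-scene generator that stands in for a trap-image corpus.

## Detection model

A single grayscale template \(T\) of size \(W \times H\) (200 x 144 by
default) slides over the grayscale frame one pixel at a time. Each placement
is scored with the mean-centered, energy-normalized cross-correlation

\[
r(x, y) \;=\; \sum_{x', y'} T'(x', y')\; I'(x + x', y + y'),
\qquad
P' \;=\; \frac{P - \bar P}{\sqrt{\sum (P - \bar P)^2}},
\]

where both the template and the image window under it are normalized the
same way. Two normalized patches have a dot product in \([-1, 1]\), and the
score is invariant under any affine change \(aI + b\) (\(a > 0\)) of scene
intensity, so fluctuations of the illuminator do not move the operating
point. Both properties require that the denominator use *mean-centered*
sums of squares; normalizing by raw second moments would break the bound
and the invariance, so trapmatch mean-centers throughout.

A window with zero variance (bare cloth, no structure) has no defined
correlation; it is assigned 0 -- below any sensible threshold --
rather than NaN, which keeps the map finite and the maximum search total.

Two implementations are provided and tested against each other to 1e-9:
a direct per-placement loop (`match_template(..., method = "direct")`,
the readable reference) and the default fast path, which computes the cross
term by 2-D FFT and the per-window means and energies with integral images.

### Padding

An insect near the frame border has no complete template window over it and
is invisible to the raw scan. `pad_image()` therefore enlarges the frame by
the template dimensions (1280 x 960 becomes 1480 x 1104), splitting the
border symmetrically -- `floor(W/2)` columns left, `floor(H/2)` rows top,
the remainder right/bottom -- so border targets gain support on every side.
The fill is the image median by default: it approximates the dark cloth and
adds no artificial contrast edge for the correlator to latch onto
(`edge`-replication and constant fill are available). A pleasant side effect
of the symmetric split is that a peak at padded-map position \((x, y)\) has
its target center at exactly \((x, y)\) in original-frame coordinates.

### Covering: one peak at a time

The raw map answers "where is the single best match"; traps catch several
insects at once. After accepting the global maximum as a detection, the
`cover_width` x `cover_height` region (defaults: the template size) around
the peak is overwritten with the map's *global minimum, recorded once before
any covering*, and the maximum search repeats until it falls below the
threshold. The loop always terminates: each accepted peak is erased, and a
`max_detections` cap (default 100, far above any plausible catch) guards
degenerate maps whose minimum is itself above threshold. With covering
disabled the detector is deliberately crippled to single-target mode, which
the ablation table uses as its baseline.

The acceptance threshold defaults to 0.4. It is the classic
efficiency/accuracy dial: lower values admit poorly matching mosquitoes
*and* debris; higher values suppress debris and drop true mosquitoes. The
default reflects the best observed compromise on real trap data of this
kind; on other data it is a configuration knob (`detection_config()`), not
a constant.

### Coordinates

All coordinates are 1-based, `x` = column and `y` = row, matching R's
indexing; images are plain numeric matrices `image[y, x]` on the 0--255
scale. A peak at map position \((x, y)\) corresponds to the template
top-left at that pixel; its center adds `floor(W/2)`, `floor(H/2)`. ROI
boxes near the frame edge are shifted inward so they stay full-size --
downstream shape analysis needs a complete window. Equal-valued maxima are
resolved in raster order (smallest row, then column) so detection output is
deterministic.

## Classification model

Each detected ROI passes through a fixed chain:

1. **Normalization** -- linear rescale to span [0, 255].
2. **Binarization** -- Otsu's threshold; the *minority-count side* is taken
   as the insect. The cloth background dominates every ROI, so this rule is
   invariant to contrast polarity (insects render bright-on-dark under the
   top illuminator, but the rule tolerates the reverse).
3. **Morphology** -- binary opening then closing with a 3 x 3 square
   element, the smallest useful denoiser. Larger elements visibly erode the
   1--3 px legs and wing edges that carry the discriminating signal.
4. **Largest component** -- connected components under 8-connectivity (thin
   diagonal appendages must stay attached); equal-area ties go to the
   component reached first in raster order.
5. **Shape features** -- pixel-count descriptors: `area` is the number of
   pixels in the filled component (interior holes, e.g. between wings, are
   filled first), `perimeter` the number of contour pixels. A pixel is on
   the contour when one of its 4 axial neighbors is background (or it
   touches the mask border). The 4-neighbor background test is the standard
   complement of 8-connected foreground: with an 8-neighbor test, diagonal
   staircases double-count and a rasterized disk's \(P^2/A\) lands some 50%
   above the isoperimetric floor \(4\pi\), whereas under the complementary
   convention it sits within about 25% of it, and the worked pixel examples
   (3 x 3 square: perimeter 8; a 1 px line: perimeter = area) are identical
   under both.
6. **Decision** -- mosquito iff `perimeter/area >= theta1` **and**
   `perimeter^2/area >= theta2` (inclusive). The first ratio is
   size-sensitive (a mosquito is simply smaller-bodied than a bee at fixed
   capture distance); the second is dimensionless and captures pure
   shape/thinness. Combining both discriminates better than shape alone.

ROIs whose mask comes out empty are labeled `other`: no insect evidence, no
features.

### Threshold calibration

No published boundary values exist for the two ratios, so the defaults are
calibrated reproducibly: 200 seeded synthetic silhouettes (100 per class,
pose-jittered, noisy) are pushed through the pipeline and each threshold is
set to the midpoint of the two class means
(`calibrate_shape_thresholds(n = 200, seed = 42)`), giving
`theta1 = 0.1734`, `theta2 = 25.2`. On the generator's defaults the class
distributions of `perimeter/area` are disjoint by a factor of about two
(mosquitoes roughly 0.21--0.29, bees 0.10--0.12), so the midpoint is not a
sensitive choice.

## Evaluation

With ground truth available, detections are matched one-to-one to annotated
insects greedily by ascending center distance, within a tolerance of
`W/2 = 100` px. A mosquito-labeled detection on a mosquito is a true
positive; a mosquito with no mosquito-labeled match is a false negative; a
mosquito-labeled detection on a bee (or on nothing) is a false positive.
Then

\[
\mathrm{recall} = \frac{TP}{TP+FN},\quad
\mathrm{precision} = \frac{TP}{TP+FP},\quad
F = \frac{2\,PR}{P+R}.
\]

Zero denominators raise errors rather than silently reporting 0. The greedy
matcher is verified in tests against an exhaustive optimal-assignment oracle
on small instances; counting is per insect (not per image). The matching
rule itself is this package's (any evaluation harness needs one; manual
inspection does not).

`ablation_table()` reruns detection in three modes -- single template
matching, + covering, + covering and padding -- and tabulates detection
rates, reproducing the structure of the standard ablation: each stage only
adds detection opportunities, so rates are non-decreasing down the table.
The absolute rates depend on the scene corpus and are not comparable across
datasets; only the ordering is a property of the method.

## The synthetic generator

There is no public corpus of trap frames, so `render_scene()` /
`make_benchmark()` emulate the imaging conditions: a dark background
(intensity 30 of 255, black cloth), a linear top-to-bottom illumination
surplus (20 at the top row, the overhead illuminator), additive Gaussian
sensor noise (sigma 5; 15 in the `noisy` regime), and parametric insect
silhouettes at contrast +160: a mosquito is a 60 x 8 body ellipse with six
1--3 px legs and two narrow wing ellipses, a bee a compact 45 x 28 body
with short wings. Poses are jittered mildly (orientation sd 12 degrees --
the suction channel aligns insects with the airflow -- and scale 0.9--1.1,
the fixed capture distance keeping apparent size stable). `easy` scenes
separate insects by at least the template diagonal; `edge-cases` scenes
place one silhouette straddling a border, the regime padding exists for.
Everything is deterministic given the seed, and every rendered insect is
annotated.

What passing on this generator shows: the correlation machinery, covering,
padding, shape features and evaluation logic behave as specified under the
stated imaging model. What it does not show: robustness to real-world
nuisances the generator omits -- motion blur, specular wing reflections,
occlusion and clutter, focus variation, non-mosquito/non-bee bycatch.
Published figures on real trap data (detection rates rising from 64% to 92%
across the ablation, F-measure about 93% with classification) are
properties of a specific 122-image corpus and are deliberately not
reproduction targets; the corresponding tests assert orderings and
synthetic-benchmark performance instead.

## Numerical choices and degenerate inputs

* All correlation arithmetic is double precision regardless of input depth;
  FFT and integral-image results clamp to \([-1, 1]\) (round-off can
  overshoot by ~1e-12) and are tested against the direct loop at 1e-9.
* Window energies below 1e-7 (intensity units squared; any real 8-bit
  variation yields about 1 or more) count as constant windows.
* Constant template: an error -- matching is meaningless.
* Covered regions are clipped at map borders; peak ties break in raster
  order; the covering fill is the pre-covering global minimum, never
  recomputed.
* Problem sizes in the shipped tests: full-size frames (1280 x 960) for the
  acceptance-level properties, with batches of 10-50 scenes; small toy
  scenes for the unit-level detection logic. The FFT path makes a full-size
  match about a second of work.

## Known limitations

* Single fixed template: no rotation or scale search. The pose jitter the
  generator applies (about +/-15 degrees) is within what the correlator
  absorbs; a sideways insect would be missed, exactly as with the original
  method.
* Two classes only; the shape rule is a linear threshold pair, not a
  learned classifier.
* The greedy matcher can differ from optimal assignment when targets crowd
  within the matching tolerance; tests pin agreement only in the
  well-separated regime the trap geometry makes typical.
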