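#' Rescale an ROI to the full 8-bit range
#'
#' Linearly maps intensities so the minimum becomes 0 and the maximum 255,
#' giving the Otsu binarization a consistent dynamic range regardless of the
#' local illumination of the trap scene. A constant ROI maps to all zeros.
#'
#' @param roi Grayscale matrix.
#' @return Matrix of the same size with values in \[0, 255\].
#' @export
normalize_roi <- function(roi) {
  assert_gray(roi, "roi")
  lo <- min(roi); hi <- max(roi)
  if (hi - lo < 1e-12) return(matrix(0, nrow(roi), ncol(roi)))
  (roi - lo) / (hi - lo) * 255
}

#' Segment the insect from the background
#'
#' Otsu's threshold splits the normalized ROI into two intensity classes; the
#' side with the smaller pixel count is taken as the insect. Trap scenes have
#' a dominant cloth background, so the insect is always the minority class --
#' this makes the rule invariant to contrast polarity (bright insect on dark
#' cloth or the reverse).
#'
#' @param roi Normalized grayscale matrix (see [normalize_roi()]).
#' @return Binary 0/1 matrix of the same size (1 = insect).
#' @export
binarize <- function(roi) {
  assert_gray(roi, "roi")
  if (max(roi) - min(roi) < 1e-12)
    return(matrix(0L, nrow(roi), ncol(roi)))
  thr <- EBImage::otsu(roi / 255) * 255
  hi <- roi > thr
  fg <- if (sum(hi) <= sum(!hi)) hi else !hi
  matrix(as.integer(fg), nrow(roi), ncol(roi))
}

#' Morphological cleanup of a binary mask
#'
#' Binary opening followed by closing with a square structuring element.
#' The default 3x3 element removes isolated noise pixels while preserving the
#' main blob; larger elements would erase the thin leg and wing structures
#' that the shape features rely on.
#'
#' @param mask Binary 0/1 matrix.
#' @param size Odd side length of the square structuring element.
#' @return Cleaned binary 0/1 matrix.
#' @export
clean_mask <- function(mask, size = 3L) {
  if (!any(mask > 0)) return(matrix(0L, nrow(mask), ncol(mask)))
  kern <- EBImage::makeBrush(as.integer(size), shape = "box")
  out <- EBImage::closing(EBImage::opening(mask, kern), kern)
  matrix(as.integer(out > 0.5), nrow(mask), ncol(mask))
}

# 8-connected component labels, assigned in raster order (top row first,
# left to right), so label 1 is the component whose topmost-leftmost pixel
# comes first.
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  fg <- which(mask > 0)
  if (!length(fg)) return(lab)
  r <- ((fg - 1L) %% h) + 1L
  c <- ((fg - 1L) %/% h) + 1L
  fg <- fg[order(r, c)]
  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  current <- 0L
  for (s in fg) {
    if (lab[s] != 0L) next
    current <- current + 1L
    lab[s] <- current
    frontier <- s
    while (length(frontier)) {
      fr <- ((frontier - 1L) %% h) + 1L
      fc <- ((frontier - 1L) %/% h) + 1L
      nr <- rep(fr, each = 8L) + dr
      nc <- rep(fc, each = 8L) + dc
      ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
      idx <- unique((nc[ok] - 1L) * h + nr[ok])
      idx <- idx[mask[idx] > 0 & lab[idx] == 0L]
      lab[idx] <- current
      frontier <- idx
    }
  }
  lab
}

#' Keep only the largest connected component
#'
#' Components use 8-connectivity so that diagonal runs of thin appendages
#' stay attached to the body. Equal-area ties go to the component whose
#' topmost-leftmost pixel comes first in raster order. An empty mask passes
#' through empty.
#'
#' @param mask Binary 0/1 matrix.
#' @return Binary 0/1 matrix containing a single component (or all zeros).
#' @export
largest_component <- function(mask) {
  lab <- label_components(mask)
  if (!any(lab > 0L)) return(matrix(0L, nrow(mask), ncol(mask)))
  areas <- tabulate(lab[lab > 0L])
  # labels are assigned in raster order, so which.max picks the raster-first
  # component among equal areas
  keep <- which.max(areas)
  matrix(as.integer(lab == keep), nrow(mask), ncol(mask))
}

# Foreground pixels that touch background or the mask border. Components are
# 8-connected, so the complementary (digitally consistent) convention applies
# to the contour: a pixel is on the edge when one of its 4 axial neighbors is
# background. With zero-padding the border case falls out automatically.
# (An 8-neighbor background test would inflate diagonal staircases and push a
# disk's perimeter^2/area far above the isoperimetric floor.)
edge_pixels <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(0L, h + 2L, w + 2L)
  pad[2L:(h + 1L), 2L:(w + 1L)] <- as.integer(mask > 0)
  nb_min <- matrix(1L, h, w)
  for (k in 1:4) {
    dr <- c(-1L, 1L, 0L, 0L)[k]; dc <- c(0L, 0L, -1L, 1L)[k]
    nb_min <- pmin(nb_min, pad[(2L + dr):(h + 1L + dr),
                               (2L + dc):(w + 1L + dc), drop = FALSE])
  }
  (mask > 0) & (nb_min == 0L)
}

#' Pixel-count perimeter and area shape features
#'
#' Uses the pixel-count definitions of the contour descriptors: `area` is the
#' number of pixels contained in the contour (the filled component -- interior
#' holes are filled first) and `perimeter` is the number of pixels on the
#' contour's edge (foreground pixels with an axial neighbor in the background
#' or on the mask border; the 4-neighbor background test is the consistent
#' complement of 8-connected components). Two ratios are derived:
#' `ratio1 = perimeter / area`
#' (size-sensitive) and `ratio2 = perimeter^2 / area` (dimensionless, shape
#' only). Thin-limbed silhouettes score high on both; compact blobs score
#' low -- a disk approaches the isoperimetric floor of 4 * pi for `ratio2`.
#'
#' @param component Non-empty binary 0/1 matrix (typically the output of
#'   [largest_component()]).
#' @return An object of class `shape_features`: list with `perimeter`, `area`,
#'   `ratio1`, `ratio2`.
#' @export
#' @examples
#' sq <- matrix(0L, 5, 5); sq[2:4, 2:4] <- 1L
#' shape_features(sq)  # area 9, perimeter 8
shape_features <- function(component) {
  if (!any(component > 0))
    stop_trapmatch("shape features are undefined for an empty component",
                   "trapmatch_empty_mask")
  filled <- EBImage::fillHull(matrix(as.integer(component > 0),
                                     nrow(component), ncol(component)))
  filled <- matrix(as.integer(filled > 0), nrow(component), ncol(component))
  area <- sum(filled)
  perimeter <- sum(edge_pixels(filled))
  structure(list(perimeter = perimeter, area = area,
                 ratio1 = perimeter / area,
                 ratio2 = perimeter^2 / area),
            class = "shape_features")
}

#' @export
print.shape_features <- function(x, ...) {
  cat(sprintf("shape features: perimeter %d, area %d, P/A %.4f, P^2/A %.2f\n",
              x$perimeter, x$area, x$ratio1, x$ratio2))
  invisible(x)
}

#' Default decision thresholds for the mosquito rule
#'
#' Midpoints between the mosquito-class and bee-class feature means measured
#' on 200 seeded silhouettes from the synthetic generator at its default
#' parameters (see [calibrate_shape_thresholds()], which recomputes them).
#'
#' @return Named vector `c(theta1, theta2)` for `ratio1` and `ratio2`.
#' @export
default_shape_thresholds <- function() {
  c(theta1 = 0.1734, theta2 = 25.2)
}

#' Classify a silhouette as mosquito or other
#'
#' The decision combines the size-sensitive and the dimensionless descriptor:
#' the label is `"mosquito"` iff `ratio1 >= theta1` **and** `ratio2 >= theta2`
#' (both comparisons inclusive). Slender bodies with thin appendages exceed
#' both thresholds; compact bee-like bodies fall below.
#'
#' @param features A [shape_features()] object.
#' @param theta1,theta2 Decision thresholds on `ratio1` and `ratio2`.
#' @return Character scalar, `"mosquito"` or `"other"`.
#' @export
classify_shape <- function(features,
                           theta1 = default_shape_thresholds()[["theta1"]],
                           theta2 = default_shape_thresholds()[["theta2"]]) {
  if (!inherits(features, "shape_features"))
    stop_trapmatch("`features` must come from shape_features()",
                   "trapmatch_bad_input")
  if (features$ratio1 >= theta1 && features$ratio2 >= theta2)
    "mosquito" else "other"
}

#' Run the full shape pipeline on one ROI
#'
#' Normalization, Otsu binarization, morphological cleanup, largest-component
#' extraction, shape features, and the threshold decision, in order. An ROI
#' whose mask comes out empty (no insect evidence) is labeled `"other"` with
#' `NULL` features.
#'
#' @param roi Grayscale ROI matrix.
#' @param theta1,theta2 Decision thresholds (see [classify_shape()]).
#' @param morph_size Structuring-element size for [clean_mask()].
#' @param keep_stages Return the intermediate images (for debugging panels).
#' @return List with `label`, `features`, and (if requested) `stages`.
#' @export
classify_roi <- function(roi,
                         theta1 = default_shape_thresholds()[["theta1"]],
                         theta2 = default_shape_thresholds()[["theta2"]],
                         morph_size = 3L, keep_stages = FALSE) {
  norm <- normalize_roi(roi)
  mask <- binarize(norm)
  cleaned <- clean_mask(mask, morph_size)
  comp <- largest_component(cleaned)
  if (!any(comp > 0)) {
    out <- list(label = "other", features = NULL)
  } else {
    feats <- shape_features(comp)
    out <- list(label = classify_shape(feats, theta1, theta2),
                features = feats)
  }
  if (keep_stages)
    out$stages <- list(normalized = norm, binarized = mask,
                       cleaned = cleaned, component = comp)
  out
}

#' Calibrate the decision thresholds on synthetic silhouettes
#'
#' Renders `n` seeded insects (half mosquito-class, half bee-class) with the
#' synthetic generator's default appearance, runs each through the shape
#' pipeline, and sets each threshold to the midpoint between the two class
#' means of the corresponding ratio. [default_shape_thresholds()] stores the
#' values this yields at `n = 200, seed = 42`.
#'
#' @param n Total number of silhouettes (split evenly between classes).
#' @param seed RNG seed controlling pose jitter and noise.
#' @param noise_sigma Additive Gaussian noise level of the rendered ROIs.
#' @return Named vector `c(theta1, theta2)` plus attribute `"class_means"`.
#' @export
calibrate_shape_thresholds <- function(n = 200L, seed = 42L, noise_sigma = 5) {
  feats <- synthetic_shape_features(n = n, seed = seed,
                                    noise_sigma = noise_sigma)
  mu <- stats::aggregate(feats[c("ratio1", "ratio2")],
                         by = list(species = feats$species), FUN = mean)
  th <- c(theta1 = mean(mu$ratio1), theta2 = mean(mu$ratio2))
  attr(th, "class_means") <- mu
  th
}

#' Shape features of seeded synthetic silhouettes
#'
#' Helper shared by calibration and the separation diagnostics: renders `n`
#' single-insect ROIs (alternating mosquito / bee, with pose jitter and
#' noise) and returns the pipeline's shape features for each.
#'
#' @inheritParams calibrate_shape_thresholds
#' @return Data frame with `species`, `perimeter`, `area`, `ratio1`, `ratio2`.
#' @export
synthetic_shape_features <- function(n = 200L, seed = 42L, noise_sigma = 5) {
  species <- rep(c("mosquito", "bee"), length.out = n)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ins <- insect_spec(species = species[i], center = c(100, 72),
                       orientation = stats::rnorm(1, 0, 12),
                       scale = stats::runif(1, 0.9, 1.1))
    spec <- scene_spec(width = 200, height = 144, insects = list(ins),
                       noise_sigma = noise_sigma, illumination_gradient = 0,
                       seed = sample.int(.Machine$integer.max - 1L, 1L))
    roi <- render_scene(spec)$image
    res <- classify_roi(roi)
    f <- res$features
    rows[[i]] <- data.frame(species = species[i],
                            perimeter = f$perimeter, area = f$area,
                            ratio1 = f$ratio1, ratio2 = f$ratio2)
  }
  do.call(rbind, rows)
}
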