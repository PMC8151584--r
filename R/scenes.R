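# RNG bookkeeping so generators are seeded without clobbering the caller's
# random stream.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

#' Specify one insect in a synthetic scene
#'
#' Parametric silhouettes stand in for the two insect classes the trap
#' discriminates. The mosquito class is a slender 60x8 body ellipse with six
#' thin legs and two narrow wing ellipses; the bee class is a compact 45x28
#' body with two short wings. The classes are built so the discriminating
#' contour features (perimeter, area) differ the way real mosquito and bee
#' silhouettes differ: thin-limbed vs. compact.
#'
#' @param species `"mosquito"` or `"bee"`.
#' @param center Length-2 vector `c(x, y)`, 1-based pixel coordinates of the
#'   body center in the scene (may be fractional).
#' @param orientation Body-axis angle in degrees (0 = horizontal).
#' @param scale Size multiplier applied to all body-part dimensions.
#' @param intensity_contrast Intensity delta of the silhouette versus the
#'   local background; positive renders bright-on-dark, negative the reverse.
#' @param allow_edge Permit the silhouette to straddle the image border
#'   (otherwise an out-of-frame insect is an error).
#' @return An object of class `insect_spec`.
#' @export
insect_spec <- function(species = c("mosquito", "bee"), center,
                        orientation = 0, scale = 1,
                        intensity_contrast = 160, allow_edge = FALSE) {
  species <- match.arg(species)
  if (length(center) != 2L || !is.numeric(center))
    stop_trapmatch("`center` must be a numeric c(x, y)", "trapmatch_bad_config")
  if (scale <= 0)
    stop_trapmatch("`scale` must be positive", "trapmatch_bad_config")
  structure(list(species = species, center = center,
                 orientation = orientation, scale = scale,
                 intensity_contrast = intensity_contrast,
                 allow_edge = isTRUE(allow_edge)),
            class = "insect_spec")
}

#' Specify a synthetic trap scene
#'
#' Emulates the imaging conditions of the trap: a dark cloth background (low
#' base intensity), a linear top illumination gradient (the illuminator sits
#' above the suction channel), small high-contrast insect silhouettes, and
#' additive Gaussian sensor noise. All randomness (noise) is fixed by `seed`.
#'
#' @param width,height Scene size in pixels (camera default 1280x960).
#' @param background_intensity Base intensity of the cloth background (0-255).
#' @param illumination_gradient Intensity surplus at the top row, decaying
#'   linearly to zero at the bottom row.
#' @param noise_sigma Standard deviation of the additive Gaussian noise, in
#'   intensity units.
#' @param insects List of [insect_spec()] objects.
#' @param seed Integer RNG seed; the same spec renders to identical bytes.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(width = 1280L, height = 960L,
                       background_intensity = 30,
                       illumination_gradient = 20, noise_sigma = 5,
                       insects = list(), seed = 1L) {
  if (width < 1 || height < 1)
    stop_trapmatch("scene dimensions must be positive", "trapmatch_bad_config")
  if (noise_sigma < 0)
    stop_trapmatch("`noise_sigma` must be >= 0", "trapmatch_bad_config")
  structure(list(width = as.integer(width), height = as.integer(height),
                 background_intensity = background_intensity,
                 illumination_gradient = illumination_gradient,
                 noise_sigma = noise_sigma, insects = insects,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

deg2rad <- function(d) d * pi / 180

# Squared distance from points (u, v) to the segment from a along unit
# direction (cos(phi), sin(phi)) of length len.
seg_dist2 <- function(u, v, a, phi, len) {
  du <- cos(phi); dv <- sin(phi)
  t <- pmin(pmax((u - a[1]) * du + (v - a[2]) * dv, 0), len)
  (u - a[1] - t * du)^2 + (v - a[2] - t * dv)^2
}

in_ellipse <- function(u, v, center, tilt, semi_a, semi_b) {
  uu <- u - center[1]; vv <- v - center[2]
  ct <- cos(tilt); st <- sin(tilt)
  a <- uu * ct + vv * st
  b <- -uu * st + vv * ct
  (a / semi_a)^2 + (b / semi_b)^2 <= 1
}

# Silhouette predicate in object coordinates (u along the body axis, v
# across it), units of pixels at scale 1.
silhouette_predicate <- function(species, u, v) {
  if (species == "mosquito") {
    hit <- (u / 30)^2 + (v / 4)^2 <= 1                      # slender body
    for (s in c(-1, 1)) {                                    # two narrow wings
      hit <- hit | in_ellipse(u, v, c(-8, s * 6), deg2rad(s * 25), 16, 3)
      for (k in seq_len(3)) {                                # three legs/side
        start <- c(c(-10, 0, 10)[k], s * c(3.5, 4, 3.5)[k])
        phi <- deg2rad(s * c(130, 90, 55)[k])
        hit <- hit | seg_dist2(u, v, start, phi, 24) <= 1.2^2
      }
    }
    hit
  } else {
    hit <- (u / 22.5)^2 + (v / 14)^2 <= 1                    # compact body
    for (s in c(-1, 1))                                      # short wings
      hit <- hit | in_ellipse(u, v, c(0, s * 15), deg2rad(s * 30), 10, 4)
    hit
  }
}

# Reach of the silhouette from its center, in object units.
silhouette_reach <- function(species) if (species == "mosquito") 36 else 24

# Rasterize one insect; returns matrix row/col indices of silhouette pixels
# in scene coordinates (possibly outside the frame) as a 2-column matrix.
insect_pixels <- function(insect, width, height) {
  R <- ceiling(silhouette_reach(insect$species) * insect$scale) + 1L
  cx <- insect$center[1]; cy <- insect$center[2]
  xs <- (round(cx) - R):(round(cx) + R)
  ys <- (round(cy) - R):(round(cy) + R)
  dx <- matrix(rep(xs - cx, each = length(ys)), length(ys), length(xs))
  dy <- matrix(rep(ys - cy, times = length(xs)), length(ys), length(xs))
  th <- deg2rad(insect$orientation)
  u <- (dx * cos(th) + dy * sin(th)) / insect$scale
  v <- (-dx * sin(th) + dy * cos(th)) / insect$scale
  hit <- silhouette_predicate(insect$species, u, v)
  idx <- which(hit, arr.ind = TRUE)
  cbind(row = ys[idx[, 1L]], col = xs[idx[, 2L]])
}

#' Render a synthetic trap scene with ground truth
#'
#' Deterministic for a fixed spec and seed. Insects are painted as hard
#' silhouettes at `background + intensity_contrast`; Gaussian noise is added
#' afterwards and the result clipped to \[0, 255\] and rounded, emulating an
#' 8-bit sensor.
#'
#' @param spec A [scene_spec()].
#' @return List with `image` (grayscale matrix) and `truth`, a data frame with
#'   one row per insect: `species`, `center_x`, `center_y`, `scale`,
#'   `orientation`, and the silhouette bounding box `x0, y0, x1, y1` clipped
#'   to the frame.
#' @export
render_scene <- function(spec) {
  if (!inherits(spec, "scene_spec"))
    stop_trapmatch("`spec` must come from scene_spec()", "trapmatch_bad_config")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(spec$seed)
  h <- spec$height; w <- spec$width
  grad <- if (h > 1)
    spec$illumination_gradient * (h - seq_len(h)) / (h - 1) else 0
  canvas <- matrix(spec$background_intensity + grad, h, w)
  truth <- list()
  for (insect in spec$insects) {
    px <- insect_pixels(insect, w, h)
    inside <- px[, "row"] >= 1L & px[, "row"] <= h &
      px[, "col"] >= 1L & px[, "col"] <= w
    if (!all(inside) && !insect$allow_edge)
      stop_trapmatch(
        "insect silhouette extends outside the frame (set allow_edge = TRUE to permit border-straddling placement)",
        "trapmatch_out_of_frame")
    if (!any(inside))
      stop_trapmatch("insect lies entirely outside the frame",
                     "trapmatch_out_of_frame")
    keep <- px[inside, , drop = FALSE]
    lin <- (keep[, "col"] - 1L) * h + keep[, "row"]
    canvas[lin] <- canvas[lin] + insect$intensity_contrast
    truth[[length(truth) + 1L]] <- data.frame(
      species = insect$species,
      center_x = insect$center[1], center_y = insect$center[2],
      scale = insect$scale, orientation = insect$orientation,
      x0 = min(keep[, "col"]), y0 = min(keep[, "row"]),
      x1 = max(keep[, "col"]), y1 = max(keep[, "row"]))
  }
  if (spec$noise_sigma > 0)
    canvas <- canvas + matrix(stats::rnorm(h * w, 0, spec$noise_sigma), h, w)
  image <- round(pmin(pmax(canvas, 0), 255))
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(species = character(), center_x = numeric(),
               center_y = numeric(), scale = numeric(),
               orientation = numeric(), x0 = integer(), y0 = integer(),
               x1 = integer(), y1 = integer())
  list(image = image, truth = truth)
}

#' Render the matching template
#'
#' A canonical insect (by default the mosquito silhouette at scale 1,
#' horizontal pose) centered in a template-sized frame on a constant
#' background, with no noise -- the reference cut-out that the detector
#' slides over every scene.
#'
#' @param insect An [insect_spec()]; its `center` is ignored (the insect is
#'   centered in the frame).
#' @param width,height Template size in pixels (default 200x144).
#' @param background Background fill intensity.
#' @return A grayscale `height x width` matrix.
#' @export
make_template <- function(insect = NULL, width = 200L, height = 144L,
                          background = 30) {
  if (is.null(insect))
    insect <- insect_spec("mosquito", center = c(0, 0))
  insect$center <- c((width + 1) / 2, (height + 1) / 2)
  spec <- scene_spec(width = width, height = height,
                     background_intensity = background,
                     illumination_gradient = 0, noise_sigma = 0,
                     insects = list(insect), seed = 0L)
  render_scene(spec)$image
}

#' Generate a seeded benchmark of annotated scenes
#'
#' Builds `n_scenes` synthetic trap scenes with per-insect ground truth.
#' Difficulty regimes: `"easy"` places 1-4 insects with centers separated by
#' at least the template diagonal and well inside the frame; `"edge-cases"`
#' places one border-straddling target per scene (plus interior ones);
#' `"noisy"` uses easy placement with tripled sensor noise. Species are drawn
#' from `mix`. Poses are jittered (orientation sd 12 degrees, scale 0.9-1.1).
#'
#' @param n_scenes Number of scenes.
#' @param mix Named proportions for species `mosquito` and `bee`.
#' @param difficulty `"easy"`, `"edge-cases"` or `"noisy"`.
#' @param seed Master seed; fixes scene seeds, counts, poses and placement.
#' @param width,height Scene size.
#' @param noise_sigma Override the regime's noise level.
#' @param dir Optional directory; when given, scenes are written as PNG plus
#'   a `manifest.json` with all annotations.
#' @return List with `scenes` (each a list `id`, `image`, `truth`) and
#'   `manifest` (all truth rows with a `scene` column).
#' @export
make_benchmark <- function(n_scenes, mix = c(mosquito = 0.6, bee = 0.4),
                           difficulty = c("easy", "edge-cases", "noisy"),
                           seed = 1L, width = 1280L, height = 960L,
                           noise_sigma = NULL, dir = NULL) {
  if (n_scenes < 1) stop_trapmatch("`n_scenes` must be >= 1",
                                   "trapmatch_bad_config")
  difficulty <- match.arg(difficulty)
  sigma <- noise_sigma %||% if (difficulty == "noisy") 15 else 5
  min_sep <- sqrt(200^2 + 144^2)      # template diagonal
  margin <- 90                        # keeps interior silhouettes off borders
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  scenes <- vector("list", n_scenes)
  for (i in seq_len(n_scenes)) {
    scene_seed <- sample.int(.Machine$integer.max - 1L, 1L)
    n_insects <- sample(1:4, 1L)
    insects <- list()
    centers <- matrix(numeric(0), 0L, 2L)
    place_interior <- function() {
      for (try in seq_len(200L)) {
        p <- c(stats::runif(1, margin, width - margin),
               stats::runif(1, margin, height - margin))
        if (!nrow(centers) ||
            all(sqrt(rowSums(sweep(centers, 2L, p)^2)) >= min_sep))
          return(p)
      }
      NULL
    }
    if (difficulty == "edge-cases") {
      side <- sample(4L, 1L)
      d <- stats::runif(1, 10, 25)    # silhouette reach ~36 px: straddles
      along_x <- stats::runif(1, margin, width - margin)
      along_y <- stats::runif(1, margin, height - margin)
      p <- switch(side,
                  c(d, along_y), c(width - d, along_y),
                  c(along_x, d), c(along_x, height - d))
      centers <- rbind(centers, p)
      insects[[1L]] <- insect_spec("mosquito", center = p,
                                   orientation = stats::rnorm(1, 0, 12),
                                   scale = stats::runif(1, 0.9, 1.1),
                                   allow_edge = TRUE)
    }
    while (length(insects) < n_insects) {
      p <- place_interior()
      if (is.null(p)) break
      centers <- rbind(centers, p)
      sp <- sample(names(mix), 1L, prob = mix)
      insects[[length(insects) + 1L]] <-
        insect_spec(sp, center = p, orientation = stats::rnorm(1, 0, 12),
                    scale = stats::runif(1, 0.9, 1.1))
    }
    spec <- scene_spec(width = width, height = height, noise_sigma = sigma,
                       insects = insects, seed = scene_seed)
    sc <- render_scene(spec)
    scenes[[i]] <- list(id = sprintf("scene_%03d", i),
                        image = sc$image, truth = sc$truth)
  }
  manifest <- do.call(rbind, lapply(scenes, function(s) {
    if (!nrow(s$truth)) return(NULL)
    cbind(scene = s$id, s$truth)
  }))
  if (is.null(manifest))
    manifest <- data.frame(scene = character())
  rownames(manifest) <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (s in scenes)
      write_gray_image(s$image, file.path(dir, paste0(s$id, ".png")))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         dataframe = "rows", digits = NA)
  }
  list(scenes = scenes, manifest = manifest)
}
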