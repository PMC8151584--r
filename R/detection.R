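#' Detection configuration
#'
#' Bundles the operating point of the detector. The default correlation
#' threshold of 0.4 trades detection rate against false alarms from debris;
#' the covering rectangle defaults to the template size so each accepted peak
#' suppresses exactly one template footprint.
#'
#' @param threshold Minimum correlation for an accepted peak, in (-1, 1).
#' @param cover_width,cover_height Size in map pixels of the region overwritten
#'   around each accepted peak; `NULL` means use the template dimensions.
#' @param enable_padding Pad the image by the template size before matching so
#'   border targets gain full correlation support.
#' @param enable_covering Iterate peak extraction; when `FALSE` at most one
#'   detection (the global maximum) is returned.
#' @param max_detections Safety bound on the number of peaks extracted.
#' @param pad_fill Border fill policy passed to [pad_image()].
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(threshold = 0.4, cover_width = NULL,
                             cover_height = NULL, enable_padding = TRUE,
                             enable_covering = TRUE, max_detections = 100L,
                             pad_fill = "median") {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= -1 || threshold >= 1)
    stop_trapmatch("`threshold` must be a single number in (-1, 1)",
                   "trapmatch_bad_config")
  for (nm in c("cover_width", "cover_height")) {
    v <- get(nm)
    if (!is.null(v) && (!is.numeric(v) || v < 1))
      stop_trapmatch(sprintf("`%s` must be >= 1", nm), "trapmatch_bad_config")
  }
  if (!is.numeric(max_detections) || max_detections < 1)
    stop_trapmatch("`max_detections` must be >= 1", "trapmatch_bad_config")
  structure(list(threshold = threshold, cover_width = cover_width,
                 cover_height = cover_height,
                 enable_padding = isTRUE(enable_padding),
                 enable_covering = isTRUE(enable_covering),
                 max_detections = as.integer(max_detections),
                 pad_fill = pad_fill),
            class = "detection_config")
}

# Clamp a W x H box centered at (cx, cy) so it lies inside a width x height
# image; returns the 1-based top-left corner.
roi_corner <- function(cx, cy, W, H, width, height) {
  x0 <- min(max(round(cx) - floor(W / 2), 1L), width - W + 1L)
  y0 <- min(max(round(cy) - floor(H / 2), 1L), height - H + 1L)
  c(x0 = x0, y0 = y0)
}

# Position of the map maximum; ties resolved first by row then by column
# (raster order) for deterministic output.
peak_position <- function(map) {
  mx <- max(map)
  pos <- which(map == mx, arr.ind = TRUE)
  pos <- pos[order(pos[, 1L], pos[, 2L]), , drop = FALSE]
  list(value = mx, y = pos[1L, 1L], x = pos[1L, 2L])
}

#' Detect insects by iterative template matching
#'
#' Computes the correlation map of the (optionally padded) image and extracts
#' targets one at a time: take the global maximum; if it is below the
#' threshold, stop; otherwise accept it as a detection and cover a
#' template-sized region around the peak with the map's global minimum
#' (recorded once, before any covering) so the next iteration finds a
#' different target. With covering disabled the procedure reduces to single
#' template matching and returns at most one detection.
#'
#' @param image Grayscale image matrix.
#' @param template Non-constant template matrix.
#' @param config A [detection_config()].
#' @return A data frame with one row per detection, ordered by decreasing
#'   score: map peak coordinates (`peak_x`, `peak_y`), the target center in
#'   original-image coordinates (`center_x`, `center_y`), the correlation
#'   `score`, and the top-left corner (`roi_x0`, `roi_y0`) of the
#'   template-sized ROI box clamped inside the image.
#' @export
#' @examples
#' tmpl <- matrix(10, 12, 16); tmpl[4:9, 5:12] <- 200
#' img <- matrix(10, 60, 80)
#' img[11:22, 11:26] <- tmpl
#' detect(img, tmpl, detection_config(threshold = 0.6))
detect <- function(image, template, config = detection_config()) {
  assert_gray(image); assert_gray(template, "template")
  if (!inherits(config, "detection_config"))
    stop_trapmatch("`config` must come from detection_config()",
                   "trapmatch_bad_config")
  H <- nrow(template); W <- ncol(template)
  off <- if (config$enable_padding) pad_offsets(template) else c(x = 0, y = 0)
  search <- if (config$enable_padding)
    pad_image(image, template, fill = config$pad_fill) else image
  map <- match_template(search, template)
  global_min <- min(map)
  cw <- as.integer(config$cover_width %||% W)
  ch <- as.integer(config$cover_height %||% H)
  rows <- list()
  repeat {
    if (length(rows) >= config$max_detections) break
    pk <- peak_position(map)
    if (pk$value < config$threshold) break
    cx <- pk$x + floor(W / 2) - off[["x"]]
    cy <- pk$y + floor(H / 2) - off[["y"]]
    corner <- roi_corner(cx, cy, W, H, ncol(image), nrow(image))
    rows[[length(rows) + 1L]] <- data.frame(
      peak_x = pk$x, peak_y = pk$y, center_x = cx, center_y = cy,
      score = pk$value, roi_x0 = corner[["x0"]], roi_y0 = corner[["y0"]])
    if (!config$enable_covering) break
    y0 <- max(1L, pk$y - floor(ch / 2))
    x0 <- max(1L, pk$x - floor(cw / 2))
    map[y0:min(nrow(map), y0 + ch - 1L),
        x0:min(ncol(map), x0 + cw - 1L)] <- global_min
  }
  if (!length(rows))
    return(data.frame(peak_x = integer(), peak_y = integer(),
                      center_x = numeric(), center_y = numeric(),
                      score = numeric(), roi_x0 = integer(),
                      roi_y0 = integer()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare detection with padding off and on
#'
#' Runs [detect()] twice on the same scene, without and with border padding,
#' and returns the two detection counts. Targets whose template window
#' extends past the image border are only recoverable in the padded run.
#'
#' @inheritParams detect
#' @return Named integer vector `c(without_padding, with_padding)`.
#' @export
detect_boundary_case <- function(image, template, config = detection_config()) {
  cfg_off <- config; cfg_off$enable_padding <- FALSE
  cfg_on <- config; cfg_on$enable_padding <- TRUE
  c(without_padding = nrow(detect(image, template, cfg_off)),
    with_padding = nrow(detect(image, template, cfg_on)))
}

#' Extract the template-sized region around a detection
#'
#' Returns the `H x W` sub-image centered on the detection, shifted inward
#' where necessary so the full window stays inside the image (downstream
#' shape features need a complete window).
#'
#' @param image The original (unpadded) image the detection was produced on.
#' @param detection One row of the data frame returned by [detect()], or any
#'   list with `center_x` and `center_y`.
#' @param template Template matrix (only its dimensions are used).
#' @return An `H x W` grayscale matrix.
#' @export
extract_roi <- function(image, detection, template) {
  assert_gray(image)
  H <- nrow(template); W <- ncol(template)
  corner <- roi_corner(detection$center_x[1L], detection$center_y[1L],
                       W, H, ncol(image), nrow(image))
  image[corner[["y0"]]:(corner[["y0"]] + H - 1L),
        corner[["x0"]]:(corner[["x0"]] + W - 1L), drop = FALSE]
}
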