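#' trapmatch: insect detection and classification in trap images
#'
#' Images throughout the package are plain numeric matrices indexed
#' `image[y, x]` (row = image row, column = image column, 1-based), with
#' intensities on the 8-bit scale 0--255 but stored as doubles. Templates use
#' the same convention; `W = ncol(template)`, `H = nrow(template)`.
#'
#' @keywords internal
"_PACKAGE"

#' @importFrom stats fft nextn median rnorm runif sd
#' @importFrom utils write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_trapmatch <- function(msg, class) {
  stop(structure(class = c(class, "trapmatch_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_gray <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image))
    stop_trapmatch(sprintf("`%s` must be a numeric matrix", arg),
                   "trapmatch_bad_input")
  if (nrow(image) < 1L || ncol(image) < 1L || !all(is.finite(image)))
    stop_trapmatch(sprintf("`%s` must be non-empty with finite intensities", arg),
                   "trapmatch_bad_input")
  invisible(image)
}

#' Convert an image array to grayscale
#'
#' Single-channel input passes through unchanged; 3-channel input is reduced
#' with ITU-R BT.601 luma weights, the de-facto standard for 8-bit camera
#' imagery.
#'
#' @param image A numeric `h x w` matrix (already gray) or `h x w x 3` array.
#' @param weights Length-3 channel weights; default BT.601 (R, G, B).
#' @return A numeric `h x w` matrix of intensities.
#' @export
#' @examples
#' arr <- array(runif(12 * 10 * 3, 0, 255), dim = c(12, 10, 3))
#' g <- to_grayscale(arr)
#' dim(g)
to_grayscale <- function(image, weights = c(0.299, 0.587, 0.114)) {
  if (is.matrix(image)) {
    assert_gray(image)
    return(image)
  }
  d <- dim(image)
  if (length(d) == 3L && d[3] == 1L) return(matrix(image[, , 1L], d[1], d[2]))
  if (length(d) != 3L || d[3] != 3L)
    stop_trapmatch("expected a 2-D matrix or an array with 1 or 3 channels",
                   "trapmatch_bad_channels")
  weights <- weights / sum(weights)
  g <- image[, , 1L] * weights[1] + image[, , 2L] * weights[2] +
    image[, , 3L] * weights[3]
  matrix(g, d[1], d[2])
}

#' Padding offsets for a template
#'
#' The border added by [pad_image()] is split symmetrically:
#' `floor(W/2)` columns on the left and `floor(H/2)` rows on top (the
#' remainder goes right/bottom), so a map coordinate in the padded image
#' converts back to original-image coordinates by subtracting these offsets.
#'
#' @param template Template matrix.
#' @return Named numeric vector `c(x = floor(W/2), y = floor(H/2))`.
#' @export
pad_offsets <- function(template) {
  c(x = floor(ncol(template) / 2), y = floor(nrow(template) / 2))
}

#' Pad an image by the template dimensions
#'
#' Enlarges the search image by the template's width and height (a 1280x960
#' image with a 200x144 template becomes 1480x1104) so that insects near the
#' border obtain full correlation support. The original image sits centered;
#' the added border is filled with the image median by default, which
#' approximates the dark cloth background of the trap without introducing
#' artificial high-contrast edges.
#'
#' @param image Grayscale image matrix.
#' @param template Template matrix (only its dimensions are used).
#' @param fill Border fill policy: `"median"`, `"edge"` (replicate the nearest
#'   edge pixel) or `"constant"`.
#' @param value Fill intensity when `fill = "constant"`.
#' @return A `(h + H) x (w + W)` matrix containing `image` at offset
#'   [pad_offsets()].
#' @export
pad_image <- function(image, template, fill = c("median", "edge", "constant"),
                      value = 0) {
  assert_gray(image)
  assert_gray(template, "template")
  fill <- match.arg(fill)
  h <- nrow(image); w <- ncol(image)
  H <- nrow(template); W <- ncol(template)
  if (H > h || W > w)
    stop_trapmatch("template must fit within the image", "trapmatch_bad_input")
  top <- floor(H / 2); left <- floor(W / 2)
  if (fill == "edge") {
    ri <- pmin(pmax(seq_len(h + H) - top, 1L), h)
    ci <- pmin(pmax(seq_len(w + W) - left, 1L), w)
    return(image[ri, ci, drop = FALSE])
  }
  bg <- if (fill == "median") stats::median(image) else value
  out <- matrix(bg, h + H, w + W)
  out[top + seq_len(h), left + seq_len(w)] <- image
  out
}

#' Mean-center and energy-normalize a patch
#'
#' Subtracts the patch mean and divides by the square root of the sum of
#' squared mean-centered values, so the output has zero sum and unit sum of
#' squares. Two patches normalized this way have a dot product in
#' \[-1, 1\] -- the correlation coefficient used for matching -- and the
#' normalization makes matching invariant to affine changes of illumination.
#'
#' @param patch Numeric matrix with at least 2 pixels.
#' @return Normalized matrix of the same dimensions.
#' @export
normalize_patch <- function(patch) {
  assert_gray(patch, "patch")
  if (length(patch) < 2L)
    stop_trapmatch("patch must have at least 2 pixels", "trapmatch_bad_input")
  centered <- patch - mean(patch)
  energy <- sum(centered * centered)
  if (energy < 1e-7)
    stop_trapmatch("constant patch has no contrast to normalize",
                   "trapmatch_degenerate_patch")
  centered / sqrt(energy)
}

# Sliding-window sums of all H x W windows via an integral image.
window_sums <- function(m, H, W) {
  h <- nrow(m); w <- ncol(m)
  P <- matrix(0, h + 1L, w + 1L)
  P[-1L, -1L] <- m
  P <- apply(P, 2L, cumsum)
  P <- t(apply(P, 1L, cumsum))
  P[(H + 1L):(h + 1L), (W + 1L):(w + 1L), drop = FALSE] -
    P[1L:(h - H + 1L), (W + 1L):(w + 1L), drop = FALSE] -
    P[(H + 1L):(h + 1L), 1L:(w - W + 1L), drop = FALSE] +
    P[1L:(h - H + 1L), 1L:(w - W + 1L), drop = FALSE]
}

#' Normalized cross-correlation at one placement
#'
#' Correlation between the template and the window whose top-left corner is at
#' `(x, y)` (1-based): both patches are mean-centered and energy-normalized
#' (see [normalize_patch()]) and their dot product is returned. A constant
#' (featureless) window carries no match evidence and yields `degenerate`
#' instead of NaN.
#'
#' @param image Grayscale image matrix.
#' @param template Non-constant template matrix.
#' @param x,y Column and row (1-based) of the window's top-left pixel.
#' @param degenerate Value returned for a zero-variance window (default 0).
#' @return Correlation coefficient in \[-1, 1\].
#' @export
ncc_at <- function(image, template, x, y, degenerate = 0) {
  H <- nrow(template); W <- ncol(template)
  if (x < 1L || y < 1L || y + H - 1L > nrow(image) || x + W - 1L > ncol(image))
    stop_trapmatch("template window extends outside the image",
                   "trapmatch_bad_input")
  tn <- normalize_patch(template)
  window <- image[y:(y + H - 1L), x:(x + W - 1L), drop = FALSE]
  wn <- tryCatch(normalize_patch(window), trapmatch_degenerate_patch = function(e) NULL)
  if (is.null(wn)) return(degenerate)
  min(max(sum(tn * wn), -1), 1)
}

#' Correlation map of every template placement
#'
#' Slides the template over the image one pixel at a time (left to right, then
#' top to bottom) and records the normalized cross-correlation of every
#' placement. The value at map position `(x, y)` corresponds to the template
#' top-left at image pixel `(x, y)`; the map has
#' `(width - W + 1) x (height - H + 1)` entries and all values lie in
#' \[-1, 1\].
#'
#' The default `"fft"` method computes the cross term with a 2-D FFT and the
#' window means/energies with integral images; `"direct"` evaluates
#' [ncc_at()] at every placement and serves as the plain-loop reference.
#' Both agree to within 1e-9.
#'
#' @inheritParams ncc_at
#' @param method `"fft"` (fast) or `"direct"` (reference loop).
#' @return Matrix of correlation coefficients, indexed `map[y, x]`.
#' @export
match_template <- function(image, template, method = c("fft", "direct"),
                           degenerate = 0) {
  assert_gray(image); assert_gray(template, "template")
  method <- match.arg(method)
  h <- nrow(image); w <- ncol(image)
  H <- nrow(template); W <- ncol(template)
  if (H > h || W > w)
    stop_trapmatch("template must fit within the image", "trapmatch_bad_input")
  tc <- template - mean(template)
  et <- sum(tc * tc)
  if (et < 1e-7)
    stop_trapmatch("constant template cannot be matched",
                   "trapmatch_degenerate_patch")
  if (method == "direct") {
    out <- matrix(0, h - H + 1L, w - W + 1L)
    for (y in seq_len(h - H + 1L))
      for (x in seq_len(w - W + 1L))
        out[y, x] <- ncc_at(image, template, x, y, degenerate)
    return(out)
  }
  # cross term: since tc is zero-mean, sum(tc * window') = sum(tc * window)
  nh <- stats::nextn(h, c(2, 3, 5)); nw <- stats::nextn(w, c(2, 3, 5))
  A <- matrix(0, nh, nw); A[seq_len(h), seq_len(w)] <- image
  B <- matrix(0, nh, nw); B[seq_len(H), seq_len(W)] <- tc
  cc <- Re(stats::fft(stats::fft(A) * Conj(stats::fft(B)), inverse = TRUE)) /
    (nh * nw)
  num <- cc[seq_len(h - H + 1L), seq_len(w - W + 1L), drop = FALSE]
  n <- H * W
  s1 <- window_sums(image, H, W)
  s2 <- window_sums(image * image, H, W)
  energy <- pmax(s2 - s1 * s1 / n, 0)
  flat <- energy < 1e-7
  den <- sqrt(et) * sqrt(pmax(energy, 1e-300))
  out <- num / den
  out[flat] <- degenerate
  pmin(pmax(out, -1), 1)
}
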