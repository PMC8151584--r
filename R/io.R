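#' Read an image file as a grayscale matrix
#'
#' Reads PNG, TIFF or JPEG (8-bit gray or RGB) and returns intensities on the
#' 0-255 scale; color input is reduced with [to_grayscale()].
#'
#' @param path Image file path.
#' @return Grayscale matrix indexed `[y, x]`.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path))
    stop_trapmatch(sprintf("image file not found: %s", path),
                   "trapmatch_io_error")
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  # EBImage stores images [x, y(, channel)]; flip to [y, x(, channel)]
  dat <- if (length(dim(dat)) == 3L) aperm(dat, c(2L, 1L, 3L)) else t(dat)
  to_grayscale(dat * 255)
}

#' Write a grayscale matrix as an image file
#'
#' @param image Grayscale matrix on the 0-255 scale.
#' @param path Output path; the format follows the file extension (PNG, TIFF
#'   or JPEG).
#' @export
write_gray_image <- function(image, path) {
  assert_gray(image)
  EBImage::writeImage(t(pmin(pmax(image, 0), 255) / 255), path)
  invisible(path)
}

#' Export a correlation map for inspection
#'
#' CSV holds the raw coefficients. The TIFF export is a 32-bit float image of
#' `(r + 1) / 2` (coefficients rescaled from \[-1, 1\] to \[0, 1\] for
#' viewer compatibility); [read_correlation_map()] undoes the rescale.
#'
#' @param map Correlation matrix from [match_template()].
#' @param path Output path.
#' @param format `"csv"` or `"tiff"`.
#' @export
write_correlation_map <- function(map, path, format = c("csv", "tiff")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.table(map, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else {
    tiff::writeTIFF((map + 1) / 2, path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' @rdname write_correlation_map
#' @export
read_correlation_map <- function(path, format = c("csv", "tiff")) {
  format <- match.arg(format)
  if (format == "csv") {
    as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  } else {
    2 * tiff::readTIFF(path) - 1
  }
}

#' Write detection records
#'
#' @param detections Detection data frame (see [detect()] and
#'   [run_pipeline()]).
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @export
write_detections <- function(detections, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(detections, path, row.names = FALSE)
  } else {
    jsonlite::write_json(detections, path, dataframe = "rows", digits = NA)
  }
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") utils::read.csv(path)
  else jsonlite::fromJSON(path)
}

#' Read a ground-truth manifest
#'
#' Accepts the JSON manifest written by [make_benchmark()] or a flat CSV with
#' the same columns (`scene`/`image_id`, `species`, `center_x`, `center_y`).
#'
#' @param path Manifest path (.json or .csv).
#' @return Data frame of annotations.
#' @export
read_truth <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path)
  else utils::read.csv(path)
}
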