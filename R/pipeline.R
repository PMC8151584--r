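#' Pipeline configuration
#'
#' One flat configuration object covering every stage: the detector operating
#' point, the morphology element, the shape-decision thresholds and the
#' evaluation tolerance. Round-trips losslessly through a YAML file via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param threshold Correlation threshold for accepting a peak.
#' @param enable_padding,enable_covering Detector stage switches.
#' @param max_detections Per-image cap on extracted peaks.
#' @param pad_fill Border fill policy for padding.
#' @param morph_size Structuring-element size for mask cleanup.
#' @param theta1,theta2 Shape-decision thresholds (see [classify_shape()]).
#' @param match_tol Detection-to-truth matching tolerance in pixels.
#' @param seed Seed recorded for provenance of synthetic runs.
#' @param log_level `"quiet"`, `"info"` or `"debug"`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(threshold = 0.4, enable_padding = TRUE,
                            enable_covering = TRUE, max_detections = 100L,
                            pad_fill = "median", morph_size = 3L,
                            theta1 = default_shape_thresholds()[["theta1"]],
                            theta2 = default_shape_thresholds()[["theta2"]],
                            match_tol = 100, seed = 1L,
                            log_level = "info") {
  check_num <- function(value, name, lo, hi) {
    if (!is.numeric(value) || length(value) != 1L || !is.finite(value) ||
        value < lo || value > hi)
      stop_trapmatch(sprintf("invalid `%s`: must be a number in [%s, %s]",
                             name, lo, hi), "trapmatch_bad_config")
  }
  check_num(threshold, "threshold", -1 + 1e-9, 1 - 1e-9)
  check_num(max_detections, "max_detections", 1, Inf)
  check_num(morph_size, "morph_size", 1, 99)
  check_num(theta1, "theta1", 0, Inf)
  check_num(theta2, "theta2", 0, Inf)
  check_num(match_tol, "match_tol", 0, Inf)
  if (!pad_fill %in% c("median", "edge", "constant"))
    stop_trapmatch("invalid `pad_fill`: must be median, edge or constant",
                   "trapmatch_bad_config")
  if (!log_level %in% c("quiet", "info", "debug"))
    stop_trapmatch("invalid `log_level`: must be quiet, info or debug",
                   "trapmatch_bad_config")
  structure(list(threshold = threshold,
                 enable_padding = isTRUE(enable_padding),
                 enable_covering = isTRUE(enable_covering),
                 max_detections = as.integer(max_detections),
                 pad_fill = pad_fill, morph_size = as.integer(morph_size),
                 theta1 = theta1, theta2 = theta2, match_tol = match_tol,
                 seed = as.integer(seed), log_level = log_level),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config` object.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    stop_trapmatch(sprintf("config file not found: %s", path),
                   "trapmatch_io_error")
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop_trapmatch(sprintf("invalid config field(s): %s",
                           paste(unknown, collapse = ", ")),
                   "trapmatch_bad_config")
  do.call(pipeline_config, vals)
}

pipeline_log <- function(config, level, ...) {
  ranks <- c(quiet = 0L, info = 1L, debug = 2L)
  if (ranks[[config$log_level]] >= ranks[[level]])
    message(sprintf(...))
  invisible(NULL)
}

#' Run the full detect-and-classify pipeline
#'
#' For each input image: grayscale conversion, (padded) template matching
#' with iterative peak covering, ROI extraction, and the shape-based
#' mosquito/other decision. If ground truth is supplied the detections are
#' scored with recall/precision/F-measure. A file that fails to load is
#' logged and skipped; the batch continues.
#'
#' @param images Character vector of image paths, or a list of grayscale
#'   matrices (optionally named; names become image ids).
#' @param template Template matrix, or a path readable by
#'   [read_gray_image()].
#' @param config A [pipeline_config()].
#' @param truth Optional ground-truth data frame with `image_id`, `species`,
#'   `center_x`, `center_y` (a `scene` column is accepted as `image_id`).
#' @param out_dir Optional directory for `detections.csv`,
#'   `detections.json` and (with truth) `metrics.csv`.
#' @return List with `detections` (per-image rows with `image_id`, centers,
#'   score, label, and shape features), plus `counts` and `metrics` when
#'   truth was given.
#' @export
run_pipeline <- function(images, template, config = pipeline_config(),
                         truth = NULL, out_dir = NULL) {
  if (!inherits(config, "pipeline_config"))
    stop_trapmatch("`config` must come from pipeline_config()",
                   "trapmatch_bad_config")
  if (!length(images))
    stop_trapmatch("no input images", "trapmatch_bad_input")
  if (is.character(template)) template <- read_gray_image(template)
  det_cfg <- detection_config(threshold = config$threshold,
                              enable_padding = config$enable_padding,
                              enable_covering = config$enable_covering,
                              max_detections = config$max_detections,
                              pad_fill = config$pad_fill)
  ids <- if (is.character(images)) basename(images)
         else names(images) %||% sprintf("image_%03d", seq_along(images))
  if (is.list(images) && is.null(names(images))) names(images) <- ids
  all_det <- list()
  n_ok <- 0L
  for (k in seq_along(images)) {
    img <- tryCatch(
      if (is.character(images)) read_gray_image(images[[k]]) else
        to_grayscale(images[[k]]),
      error = function(e) {
        pipeline_log(config, "info", "skipping %s: %s", ids[k],
                     conditionMessage(e))
        NULL
      })
    if (is.null(img)) next
    n_ok <- n_ok + 1L
    det <- detect(img, template, det_cfg)
    if (nrow(det)) {
      labels <- character(nrow(det))
      feats <- matrix(NA_real_, nrow(det), 4L,
                      dimnames = list(NULL, c("perimeter", "area",
                                              "ratio1", "ratio2")))
      for (i in seq_len(nrow(det))) {
        roi <- extract_roi(img, det[i, ], template)
        res <- classify_roi(roi, theta1 = config$theta1,
                            theta2 = config$theta2,
                            morph_size = config$morph_size)
        labels[i] <- res$label
        if (!is.null(res$features))
          feats[i, ] <- unlist(res$features)
      }
      det$label <- labels
      det <- cbind(det, as.data.frame(feats))
      det <- cbind(image_id = ids[k], det)
      all_det[[length(all_det) + 1L]] <- det
    }
    pipeline_log(config, "debug", "%s: %d detection(s)", ids[k], nrow(det))
  }
  detections <- if (length(all_det)) do.call(rbind, all_det) else
    data.frame(image_id = character(), center_x = numeric(),
               center_y = numeric(), score = numeric(), label = character())
  rownames(detections) <- NULL
  pipeline_log(config, "info", "processed %d image(s): %d detection(s), %d mosquito(es)",
               n_ok, nrow(detections), sum(detections$label == "mosquito"))
  out <- list(detections = detections)
  if (!is.null(truth)) {
    if (is.null(truth$image_id) && !is.null(truth$scene))
      truth$image_id <- truth$scene
    out$counts <- match_to_ground_truth(detections, truth,
                                        tol = config$match_tol)
    out$metrics <- compute_metrics(out$counts)
    pipeline_log(config, "info",
                 "recall %.1f%%, precision %.1f%%, F-measure %.1f%%",
                 100 * out$metrics$recall, 100 * out$metrics$precision,
                 100 * out$metrics$f_measure)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_detections(detections, file.path(out_dir, "detections.csv"), "csv")
    write_detections(detections, file.path(out_dir, "detections.json"),
                     "json")
    if (!is.null(out$metrics)) {
      m <- out$metrics; cc <- out$counts
      utils::write.csv(
        data.frame(TP = cc$TP, FN = cc$FN, FP = cc$FP,
                   recall = m$recall, precision = m$precision,
                   f_measure = m$f_measure),
        file.path(out_dir, "metrics.csv"), row.names = FALSE)
    }
  }
  out
}
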