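# Greedy one-to-one matching of detections to ground-truth insects by center
# distance: all detection/truth pairs closer than `tol` are sorted by
# distance and assigned greedily. Returns a data frame of matched index pairs.
greedy_match <- function(det_xy, truth_xy, tol) {
  nd <- nrow(det_xy); nt <- nrow(truth_xy)
  if (!nd || !nt)
    return(data.frame(det = integer(), truth = integer()))
  d2 <- outer(seq_len(nd), seq_len(nt), function(i, j)
    (det_xy[i, 1L] - truth_xy[j, 1L])^2 + (det_xy[i, 2L] - truth_xy[j, 2L])^2)
  cand <- which(d2 <= tol^2, arr.ind = TRUE)
  if (!nrow(cand))
    return(data.frame(det = integer(), truth = integer()))
  cand <- cand[order(d2[cand]), , drop = FALSE]
  used_d <- logical(nd); used_t <- logical(nt)
  pairs <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1L]; j <- cand[k, 2L]
    if (used_d[i] || used_t[j]) next
    used_d[i] <- TRUE; used_t[j] <- TRUE
    pairs[[length(pairs) + 1L]] <- data.frame(det = i, truth = j)
  }
  if (!length(pairs)) data.frame(det = integer(), truth = integer())
  else do.call(rbind, pairs)
}

#' Confusion counts of mosquito detections against ground truth
#'
#' Detections (of any label) are matched one-to-one to ground-truth insects
#' by center distance, greedily by ascending distance, within `tol` pixels.
#' Counting then follows the mosquito-surveillance convention:
#' a mosquito-labeled detection matched to a mosquito truth is a true
#' positive; a mosquito truth without a mosquito-labeled match is a false
#' negative; a mosquito-labeled detection matched to a non-mosquito truth, or
#' matched to nothing, is a false positive.
#'
#' @param detections Data frame with `center_x`, `center_y` and optionally
#'   `label` (missing label means every detection claims "mosquito", i.e.
#'   detection-only mode) and optionally `image_id`.
#' @param truth Data frame with `center_x`, `center_y`, `species`, and
#'   optionally `image_id`; matching is restricted within each image when ids
#'   are present on both sides.
#' @param tol Maximum center distance in pixels for a match (default 100,
#'   half the template width).
#' @return An object of class `confusion_counts`: list with `TP`, `FN`, `FP`.
#' @export
match_to_ground_truth <- function(detections, truth, tol = 100) {
  if (is.null(detections$label)) detections$label <- "mosquito"
  both_ids <- !is.null(detections$image_id) && !is.null(truth$image_id)
  groups <- if (both_ids)
    unique(c(detections$image_id, truth$image_id)) else "all"
  TP <- FN <- FP <- 0L
  for (g in groups) {
    det <- if (both_ids) detections[detections$image_id == g, , drop = FALSE]
           else detections
    tr <- if (both_ids) truth[truth$image_id == g, , drop = FALSE] else truth
    pairs <- greedy_match(cbind(det$center_x, det$center_y),
                          cbind(tr$center_x, tr$center_y), tol)
    det_matched <- rep(NA_integer_, nrow(det))
    truth_matched_by <- rep(NA_integer_, nrow(tr))
    det_matched[pairs$det] <- pairs$truth
    truth_matched_by[pairs$truth] <- pairs$det
    is_mosq_det <- det$label == "mosquito"
    # detections claiming "mosquito"
    for (i in which(is_mosq_det)) {
      j <- det_matched[i]
      if (!is.na(j) && tr$species[j] == "mosquito") TP <- TP + 1L
      else FP <- FP + 1L
    }
    # mosquito truths without a mosquito-labeled match
    for (j in which(tr$species == "mosquito")) {
      i <- truth_matched_by[j]
      if (is.na(i) || !is_mosq_det[i]) FN <- FN + 1L
    }
  }
  confusion_counts(TP, FN, FP)
}

#' Construct confusion counts
#'
#' @param TP,FN,FP Non-negative integer counts of true positives, false
#'   negatives, and false positives.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, FN, FP) {
  counts <- c(TP, FN, FP)
  if (any(counts < 0) || any(counts != round(counts)))
    stop_trapmatch("confusion counts must be non-negative integers",
                   "trapmatch_bad_input")
  structure(list(TP = as.integer(TP), FN = as.integer(FN),
                 FP = as.integer(FP)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts: TP %d, FN %d, FP %d\n", x$TP, x$FN, x$FP))
  invisible(x)
}

#' Recall, precision and F-measure from confusion counts
#'
#' `recall = TP / (TP + FN)`, `precision = TP / (TP + FP)`, and the F-measure
#' is the harmonic mean `2 * precision * recall / (precision + recall)`.
#' A zero denominator makes the corresponding metric undefined and raises an
#' error rather than silently reporting 0.
#'
#' @param counts A [confusion_counts()] object.
#' @return An object of class `detection_metrics`: list with `recall`,
#'   `precision`, `f_measure` as fractions in \[0, 1\].
#' @export
#' @examples
#' m <- compute_metrics(confusion_counts(TP = 93, FN = 6, FP = 7))
#' round(100 * unlist(m), 1)  # 93.9, 93.0, 93.5
compute_metrics <- function(counts) {
  if (!inherits(counts, "confusion_counts"))
    stop_trapmatch("`counts` must come from confusion_counts()",
                   "trapmatch_bad_input")
  if (counts$TP + counts$FN == 0L)
    stop_trapmatch("recall is undefined: TP + FN is zero",
                   "trapmatch_undefined_metric")
  if (counts$TP + counts$FP == 0L)
    stop_trapmatch("precision is undefined: TP + FP is zero",
                   "trapmatch_undefined_metric")
  recall <- counts$TP / (counts$TP + counts$FN)
  precision <- counts$TP / (counts$TP + counts$FP)
  if (precision + recall == 0)
    stop_trapmatch("F-measure is undefined: precision + recall is zero",
                   "trapmatch_undefined_metric")
  f <- 2 * precision * recall / (precision + recall)
  structure(list(recall = recall, precision = precision, f_measure = f),
            class = "detection_metrics")
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat(sprintf("recall %.1f%%, precision %.1f%%, F-measure %.1f%%\n",
              100 * x$recall, 100 * x$precision, 100 * x$f_measure))
  invisible(x)
}

#' Fraction of ground-truth insects recovered by the detector
#'
#' Matches detections (regardless of class label) to truth by center distance
#' and returns matched / total, the detection-rate figure used by the
#' covering/padding ablation.
#'
#' @inheritParams match_to_ground_truth
#' @return List with `detected`, `total`, `rate`.
#' @export
detection_rate <- function(detections, truth, tol = 100) {
  both_ids <- !is.null(detections$image_id) && !is.null(truth$image_id)
  groups <- if (both_ids)
    unique(c(detections$image_id, truth$image_id)) else "all"
  detected <- 0L; total <- 0L
  for (g in groups) {
    det <- if (both_ids) detections[detections$image_id == g, , drop = FALSE]
           else detections
    tr <- if (both_ids) truth[truth$image_id == g, , drop = FALSE] else truth
    pairs <- greedy_match(cbind(det$center_x, det$center_y),
                          cbind(tr$center_x, tr$center_y), tol)
    detected <- detected + nrow(pairs)
    total <- total + nrow(tr)
  }
  list(detected = detected, total = total,
       rate = if (total > 0) detected / total else NA_real_)
}

#' Ablation of the covering and padding stages
#'
#' Runs the detector on a set of annotated scenes in three modes -- single
#' template matching (no covering, no padding), multi-target matching
#' (covering only), and the full algorithm (covering plus padding) -- and
#' tabulates the detection rate of each. Each stage only adds detection
#' opportunities, so the rates are expected to be non-decreasing down the
#' table.
#'
#' @param scenes List of scenes, each a list with `image` and `truth` (as
#'   produced by [make_benchmark()]).
#' @param template Template matrix.
#' @param config Base [detection_config()]; its covering/padding flags are
#'   overridden per mode.
#' @param tol Matching tolerance in pixels.
#' @return Data frame with columns `algorithm`, `covering`, `padding`,
#'   `detected`, `total`, `rate`.
#' @export
ablation_table <- function(scenes, template, config = detection_config(),
                           tol = 100) {
  if (!length(scenes))
    stop_trapmatch("`scenes` must contain at least one scene",
                   "trapmatch_bad_input")
  modes <- list(
    list(name = "single template matching", covering = FALSE, padding = FALSE),
    list(name = "multi-target template matching", covering = TRUE,
         padding = FALSE),
    list(name = "multi-target matching + padding", covering = TRUE,
         padding = TRUE))
  rows <- lapply(modes, function(m) {
    cfg <- config
    cfg$enable_covering <- m$covering
    cfg$enable_padding <- m$padding
    detected <- 0L; total <- 0L
    for (s in scenes) {
      det <- detect(s$image, template, cfg)
      r <- detection_rate(det, s$truth, tol)
      detected <- detected + r$detected
      total <- total + r$total
    }
    data.frame(algorithm = m$name, covering = m$covering,
               padding = m$padding, detected = detected, total = total,
               rate = if (total > 0) detected / total else NA_real_)
  })
  do.call(rbind, rows)
}
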