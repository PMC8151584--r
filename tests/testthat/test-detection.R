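# Fast detection tests use a toy bright-blob template on small scenes; the
# full-size insect generator is exercised in the scene and acceptance tests.

test_that("covering extracts every target while single mode stops at one", {
  tmpl <- toy_template()
  img <- matrix(10, 80, 120)
  img <- embed_patch(img, tmpl, 20, 15)
  img <- embed_patch(img, tmpl, 80, 50)
  multi <- detect(img, tmpl, detection_config(threshold = 0.5))
  single <- detect(img, tmpl,
                   detection_config(threshold = 0.5, enable_covering = FALSE))
  expect_equal(nrow(multi), 2L)
  expect_equal(nrow(single), 1L)
  expect_true(all(diff(multi$score) <= 0))
})

test_that("a featureless scene yields no detections", {
  tmpl <- toy_template()
  set.seed(201)
  img <- matrix(10 + rnorm(80 * 120, 0, 2), 80, 120)
  expect_equal(nrow(detect(img, tmpl)), 0L)
})

test_that("k non-overlapping embedded copies give exactly k detections at true centers", {
  tmpl <- toy_template()
  W <- ncol(tmpl); H <- nrow(tmpl)
  set.seed(202)
  positions <- list(c(10, 10), c(60, 10), c(110, 10), c(40, 45), c(100, 45))
  for (k in 2:5) {
    img <- matrix(10 + rnorm(70 * 140, 0, 1), 70, 140)
    centers <- matrix(0, k, 2)
    for (i in seq_len(k)) {
      p <- positions[[i]]
      img <- embed_patch(img, tmpl, p[1], p[2])
      centers[i, ] <- c(p[1] + floor(W / 2), p[2] + floor(H / 2))
    }
    det <- detect(img, tmpl, detection_config(threshold = 0.4))
    expect_equal(nrow(det), k)
    for (i in seq_len(k)) {
      d <- sqrt((det$center_x - centers[i, 1])^2 +
                (det$center_y - centers[i, 2])^2)
      expect_lt(min(d), sqrt((W / 2)^2 + (H / 2)^2))
    }
  }
})

test_that("padding recovers boundary targets and is inert for interior ones", {
  tmpl <- toy_template()
  set.seed(203)
  # blob straddling the left edge: half the template hangs outside
  img <- matrix(10 + rnorm(80 * 120, 0, 1), 80, 120)
  img <- embed_patch(img, tmpl, -6, 40)
  counts <- detect_boundary_case(img, tmpl, detection_config(threshold = 0.4))
  expect_equal(unname(counts), c(0L, 1L))

  # central target: padding cannot remove an interior detection
  img2 <- matrix(10 + rnorm(80 * 120, 0, 1), 80, 120)
  img2 <- embed_patch(img2, tmpl, 50, 30)
  counts2 <- detect_boundary_case(img2, tmpl, detection_config(threshold = 0.4))
  expect_equal(unname(counts2), c(1L, 1L))
})

test_that("raising the threshold never increases the number of detections", {
  tmpl <- toy_template()
  set.seed(204)
  img <- matrix(10 + rnorm(90 * 140, 0, 3), 90, 140)
  img <- embed_patch(img, tmpl, 15, 15)
  img <- embed_patch(img, tmpl, 90, 60)
  counts <- sapply(c(0.2, 0.4, 0.6, 0.8, 0.95), function(th)
    nrow(detect(img, tmpl, detection_config(threshold = th))))
  expect_true(all(diff(counts) <= 0))
})

test_that("no two peaks fall within the same covered rectangle and the cap holds", {
  tmpl <- toy_template()
  W <- ncol(tmpl); H <- nrow(tmpl)
  set.seed(205)
  img <- matrix(10 + rnorm(70 * 140, 0, 1), 70, 140)
  for (p in list(c(10, 10), c(60, 10), c(110, 10), c(40, 45)))
    img <- embed_patch(img, tmpl, p[1], p[2])
  det <- detect(img, tmpl, detection_config(threshold = 0.4))
  if (nrow(det) > 1) {
    for (i in 2:nrow(det)) for (j in 1:(i - 1)) {
      inside <- abs(det$peak_x[i] - det$peak_x[j]) < W / 2 &&
        abs(det$peak_y[i] - det$peak_y[j]) < H / 2
      expect_false(inside)
    }
  }
  capped <- detect(img, tmpl,
                   detection_config(threshold = 0.4, max_detections = 2))
  expect_lte(nrow(capped), 2L)
})

test_that("ROI boxes are template-sized, follow the centering rule, and clamp at corners", {
  # image whose pixel values encode their column index makes the extracted
  # window self-describing
  img <- matrix(rep(seq_len(1280), each = 960), 960, 1280)
  tmpl <- matrix(0, 144, 200)
  roi <- extract_roi(img, list(center_x = 641, center_y = 481), tmpl)
  expect_equal(dim(roi), c(144L, 200L))
  expect_equal(roi[1, 1], 541)    # columns 541..740 (x in [540, 740) 0-based)
  expect_equal(roi[1, 200], 740)

  clamped <- extract_roi(img, list(center_x = 5, center_y = 5), tmpl)
  expect_equal(dim(clamped), c(144L, 200L))
  expect_equal(clamped[1, 1], 1)  # shifted inward to the corner
  expect_equal(clamped[1, 200], 200)
})

test_that("detection rejects invalid configurations and degenerate templates", {
  expect_error(detection_config(threshold = 1.5), class = "trapmatch_bad_config")
  expect_error(detection_config(max_detections = 0), class = "trapmatch_bad_config")
  img <- matrix(runif(400, 0, 255), 20, 20)
  expect_error(detect(img, matrix(5, 4, 4)),
               class = "trapmatch_degenerate_patch")
})
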