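test_that("metrics match their closed forms on random counts", {
  set.seed(401)
  for (k in 1:50) {
    tp <- sample(1:200, 1); fn <- sample(0:100, 1); fp <- sample(0:100, 1)
    m <- compute_metrics(confusion_counts(tp, fn, fp))
    expect_equal(m$recall, tp / (tp + fn), tolerance = 1e-12)
    expect_equal(m$precision, tp / (tp + fp), tolerance = 1e-12)
    expect_equal(m$f_measure,
                 2 * m$precision * m$recall / (m$precision + m$recall),
                 tolerance = 1e-12)
    expect_gte(m$f_measure, min(m$recall, m$precision) - 1e-12)
    expect_lte(m$f_measure, max(m$recall, m$precision) + 1e-12)
  }
})

test_that("zero-denominator metrics raise defined errors instead of silent zeros", {
  expect_error(compute_metrics(confusion_counts(0, 0, 3)),
               class = "trapmatch_undefined_metric")
  expect_error(compute_metrics(confusion_counts(0, 5, 0)),
               class = "trapmatch_undefined_metric")
  expect_error(confusion_counts(-1, 0, 0), class = "trapmatch_bad_input")
})

test_that("ground-truth matching follows the TP/FN/FP definitions", {
  truth <- data.frame(species = "mosquito", center_x = 50, center_y = 50)
  det <- data.frame(center_x = 53, center_y = 50, label = "mosquito")
  cc <- match_to_ground_truth(det, truth, tol = 100)
  expect_equal(c(cc$TP, cc$FN, cc$FP), c(1L, 0L, 0L))

  # a mosquito-labeled detection on a bee is a false positive
  bee_truth <- data.frame(species = "bee", center_x = 50, center_y = 50)
  cc2 <- match_to_ground_truth(det, bee_truth, tol = 100)
  expect_equal(c(cc2$TP, cc2$FN, cc2$FP), c(0L, 0L, 1L))

  # a mosquito found but labeled "other" is still a miss
  det3 <- data.frame(center_x = 50, center_y = 50, label = "other")
  cc3 <- match_to_ground_truth(det3, truth, tol = 100)
  expect_equal(c(cc3$TP, cc3$FN, cc3$FP), c(0L, 1L, 0L))
})

test_that("greedy matching agrees with exhaustive assignment on well-separated scenes", {
  set.seed(402)
  tol <- 50
  for (k in 1:20) {
    nt <- sample(1:5, 1)
    # separation > 2 * tol guarantees a unique optimal assignment
    truth_xy <- cbind(x = seq_len(nt) * (2 * tol + 20), y = 100)
    keep <- runif(nt) < 0.8
    det_xy <- truth_xy[keep, , drop = FALSE] +
      matrix(runif(2 * sum(keep), -20, 20), ncol = 2)
    truth <- data.frame(species = "mosquito", center_x = truth_xy[, 1],
                        center_y = truth_xy[, 2])
    det <- data.frame(center_x = det_xy[, 1], center_y = det_xy[, 2],
                      label = rep("mosquito", nrow(det_xy)))
    cc <- match_to_ground_truth(det, truth, tol = tol)
    best <- brute_max_matches(det_xy, truth_xy, tol)
    expect_equal(cc$TP, best)
    expect_equal(cc$FN, nt - best)
    expect_equal(cc$FP, nrow(det_xy) - best)

    # permuting detection order changes nothing
    perm <- sample(nrow(det))
    cc_perm <- match_to_ground_truth(det[perm, , drop = FALSE], truth,
                                     tol = tol)
    expect_identical(unclass(cc), unclass(cc_perm))
  }
})

test_that("detection-rate ablation orders single <= covering <= full", {
  tmpl <- toy_template()
  set.seed(403)
  scenes <- list()
  for (i in 1:6) {
    img <- matrix(10 + rnorm(80 * 120, 0, 1), 80, 120)
    truth <- list()
    # two interior targets
    for (p in list(c(15, 12), c(80, 50))) {
      img <- embed_patch(img, tmpl, p[1], p[2])
      truth[[length(truth) + 1]] <- data.frame(
        species = "mosquito", center_x = p[1] + 8, center_y = p[2] + 6)
    }
    # one straddling the border
    img <- embed_patch(img, tmpl, -6, 30)
    truth[[length(truth) + 1]] <- data.frame(
      species = "mosquito", center_x = 2, center_y = 36)
    scenes[[i]] <- list(image = img, truth = do.call(rbind, truth))
  }
  tab <- ablation_table(scenes, tmpl, detection_config(threshold = 0.4),
                        tol = 10)
  expect_equal(nrow(tab), 3L)
  expect_true(tab$rate[1] <= tab$rate[2])
  expect_true(tab$rate[2] <= tab$rate[3])
  expect_gt(tab$rate[3], tab$rate[1])   # covering + padding recover targets

  # with a single central target per scene the stages are inert
  central <- lapply(1:3, function(i) {
    img <- matrix(10, 80, 120)
    img <- embed_patch(img, tmpl, 50, 30)
    list(image = img,
         truth = data.frame(species = "mosquito", center_x = 58,
                            center_y = 36))
  })
  tab2 <- ablation_table(central, tmpl, detection_config(threshold = 0.4),
                         tol = 10)
  expect_equal(tab2$rate, rep(1, 3))

  expect_error(ablation_table(list(), tmpl), class = "trapmatch_bad_input")
})
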