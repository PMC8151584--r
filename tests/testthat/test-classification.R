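test_that("ROI normalization spans the 8-bit range and degrades gracefully", {
  roi <- matrix(c(50, 100, 150, 120), 2, 2)
  norm <- normalize_roi(roi)
  expect_equal(norm[2, 1], 127.5)      # pixel 100 in a [50, 150] span
  expect_equal(range(norm), c(0, 255))

  spanning <- matrix(c(0, 255, 100, 30), 2, 2)
  expect_equal(normalize_roi(spanning), spanning)

  expect_equal(normalize_roi(matrix(77, 3, 4)), matrix(0, 3, 4))
})

test_that("binarization picks the minority side regardless of contrast polarity", {
  set.seed(301)
  roi <- matrix(20, 40, 50)
  roi[15:22, 20:31] <- 230                      # ~4.8% insect pixels
  mask <- binarize(normalize_roi(roi))
  frac <- mean(mask)
  expect_gt(frac, 0.03); expect_lt(frac, 0.07)

  inverted <- 255 - roi                         # dark insect on bright cloth
  mask_inv <- binarize(normalize_roi(inverted))
  expect_identical(mask, mask_inv)

  expect_equal(binarize(matrix(0, 5, 5)), matrix(0L, 5, 5))
})

test_that("morphological cleanup removes speckle but preserves the main blob", {
  m <- matrix(0L, 60, 60)
  m[10:49, 10:49] <- 1L                          # solid 40x40 square
  m[3, 3] <- m[55, 5] <- m[5, 55] <- 1L          # isolated speckle
  cleaned <- clean_mask(m, 3)
  expect_equal(cleaned[3, 3] + cleaned[55, 5] + cleaned[5, 55], 0L)
  expect_lt(abs(sum(cleaned) - 1600) / 1600, 0.05)

  expect_equal(clean_mask(matrix(0L, 10, 10)), matrix(0L, 10, 10))

  disk <- disk_mask(15)
  expect_lt(abs(sum(clean_mask(disk, 3)) - sum(disk)) / sum(disk), 0.02)
})

test_that("largest-component selection is 8-connected with a raster tie rule", {
  m <- matrix(0L, 30, 30)
  m[2:11, 2:11] <- 1L                            # area 100
  m[20:24, 20:25] <- 1L                          # area 30
  kept <- largest_component(m)
  expect_equal(sum(kept), 100)
  expect_equal(kept[2, 2], 1L); expect_equal(kept[20, 20], 0L)

  single <- matrix(0L, 10, 10); single[3:6, 3:6] <- 1L
  expect_equal(largest_component(single), single)

  # diagonal chain is one component under 8-connectivity
  diag_m <- matrix(0L, 8, 8); for (i in 1:8) diag_m[i, i] <- 1L
  expect_equal(sum(largest_component(diag_m)), 8)

  # equal areas: the component reached first in raster order wins
  tie <- matrix(0L, 10, 20)
  tie[5:6, 15:16] <- 1L
  tie[2:3, 2:3] <- 1L                            # earlier raster position
  kept_tie <- largest_component(tie)
  expect_equal(kept_tie[2, 2], 1L)
  expect_equal(kept_tie[5, 15], 0L)
})

test_that("pixel-count perimeter and area follow their definitions", {
  sq <- matrix(0L, 5, 5); sq[2:4, 2:4] <- 1L
  f <- shape_features(sq)
  expect_equal(f$area, 9); expect_equal(f$perimeter, 8)
  expect_equal(f$ratio1, 8 / 9); expect_equal(f$ratio2, 64 / 9)

  px <- matrix(0L, 3, 3); px[2, 2] <- 1L
  f1 <- shape_features(px)
  expect_equal(unlist(f1[c("perimeter", "area", "ratio1", "ratio2")]),
               c(perimeter = 1, area = 1, ratio1 = 1, ratio2 = 1))

  line <- matrix(0L, 5, 24); line[3, 3:22] <- 1L
  fl <- shape_features(line)
  expect_equal(fl$area, 20); expect_equal(fl$perimeter, 20)
  expect_equal(fl$ratio1, 1.0)

  # interior holes are filled before counting
  ring <- matrix(0L, 12, 12); ring[3:10, 3:10] <- 1L; ring[5:8, 5:8] <- 0L
  expect_equal(shape_features(ring)$area, 64)

  expect_error(shape_features(matrix(0L, 4, 4)),
               class = "trapmatch_empty_mask")
})

test_that("the dimensionless ratio sits near the isoperimetric floor for disks", {
  for (r in c(10, 14, 18)) {
    f <- shape_features(disk_mask(r))
    expect_lt(abs(f$ratio2 - 4 * pi) / (4 * pi), 0.40)
  }
  # a 1-pixel-thin shape of the same area maximizes perimeter at fixed area
  disk <- disk_mask(10)
  area <- sum(disk)
  skel <- matrix(0L, 6, area + 4); skel[3, 3:(area + 2)] <- 1L
  expect_gt(shape_features(skel)$ratio2, shape_features(disk)$ratio2)
})

test_that("feature scaling behaves as perimeter ~ s, area ~ s^2", {
  # the same shape rendered at twice the size: perimeter/area halves while
  # the dimensionless ratio stays put
  f1 <- shape_features(disk_mask(9))
  f2 <- shape_features(disk_mask(18))
  expect_lt(f2$ratio1, f1$ratio1)
  expect_lt(abs(f2$ratio2 - f1$ratio2) / f1$ratio2, 0.15)

  sil <- function(s) {
    sc <- render_scene(scene_spec(width = 300, height = 300,
                                  illumination_gradient = 0, noise_sigma = 0,
                                  insects = list(insect_spec("mosquito",
                                                             c(150, 150),
                                                             scale = s)),
                                  seed = 1))$image
    shape_features(largest_component(binarize(normalize_roi(sc))))
  }
  g1 <- sil(1); g2 <- sil(2)
  expect_lt(g2$ratio1, g1$ratio1)
  expect_lt(abs(g2$ratio2 - g1$ratio2) / g1$ratio2, 0.15)
})

test_that("the decision rule is inclusive at the boundary and rejects disks", {
  sq <- matrix(0L, 5, 5); sq[2:4, 2:4] <- 1L
  f <- shape_features(sq)
  expect_equal(classify_shape(f, theta1 = f$ratio1, theta2 = f$ratio2),
               "mosquito")
  expect_equal(classify_shape(f, theta1 = f$ratio1 + 1e-9,
                              theta2 = f$ratio2), "other")

  disk <- shape_features(disk_mask(20))
  expect_equal(classify_shape(disk), "other")
})

test_that("rendered silhouettes classify to their generator class deterministically", {
  mosq <- render_scene(scene_spec(width = 200, height = 144,
                                  illumination_gradient = 0,
                                  insects = list(insect_spec("mosquito",
                                                             c(100, 72))),
                                  seed = 11))$image
  bee <- render_scene(scene_spec(width = 200, height = 144,
                                 illumination_gradient = 0,
                                 insects = list(insect_spec("bee",
                                                            c(100, 72))),
                                 seed = 12))$image
  res_m <- classify_roi(mosq); res_b <- classify_roi(bee)
  expect_equal(res_m$label, "mosquito")
  expect_equal(res_b$label, "other")
  expect_gt(res_m$features$ratio1, res_b$features$ratio1)
  expect_gt(res_m$features$ratio2, res_b$features$ratio2)

  # identical ROI bytes, identical outcome
  expect_identical(classify_roi(mosq), res_m)

  # an empty ROI produces "other" with no features rather than an error
  flat <- classify_roi(matrix(40, 144, 200))
  expect_equal(flat$label, "other")
  expect_null(flat$features)
})
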