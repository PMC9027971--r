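test_that("fg/bg-averaged Dice matches set arithmetic on constructed cases", {
  g <- matrix(0, 100, 100); g[11:20, 11:20] <- 1
  expect_equal(dice_score(g, g), 1)
  p <- matrix(0, 100, 100); p[51:60, 51:60] <- 1
  # disjoint 10x10 squares: fg Dice 0, bg Dice 9800/9900
  expect_equal(dice_score(p, g), (0 + 2 * 9800 / (9900 + 9900)) / 2)
  expect_equal(dice_score(1 - g, g), 0)         # complement: fg 0, bg 0
  z <- matrix(0, 50, 50)
  expect_equal(dice_score(z, z), 1)             # both-empty convention
  expect_error(dice_score(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("ASSD matches the nearest-point formula and is symmetric", {
  C1 <- cbind(seq(0, 100, by = 0.5), 0)
  expect_equal(assd(C1, C1, spacing = NA), 0, ignore_attr = TRUE)
  C2 <- cbind(seq(0, 100, by = 0.5), 5)
  expect_equal(assd(C1, C2, spacing = NA), 5,    # matched parallel segments
               ignore_attr = TRUE)
  set.seed(5)
  A <- matrix(runif(40, 0, 50), ncol = 2)
  B <- matrix(runif(30, 0, 50), ncol = 2)
  expect_equal(assd(A, B, spacing = NA), assd(B, A, spacing = NA),
               ignore_attr = TRUE)
  # brute-force oracle in R
  dmat <- as.matrix(stats::dist(rbind(A, B)))[1:20, 21:35]
  oracle <- (sum(apply(dmat, 1, min)) + sum(apply(dmat, 2, min))) / 35
  expect_equal(assd(A, B, spacing = NA), oracle, ignore_attr = TRUE)
  expect_error(assd(A[0, , drop = FALSE], B, spacing = NA), "empty")
})

test_that("ASSD converts to mm when calibrated", {
  C1 <- cbind(seq(0, 20, 0.5), 0); C2 <- cbind(seq(0, 20, 0.5), 4)
  v <- assd(C1, C2, spacing = NA, cal = calibration(0.25, "manual"))
  expect_equal(as.numeric(v), 4)
  expect_equal(attr(v, "mm"), 1)
})

test_that("keypoint Euclidean distance and mm conversion", {
  expect_equal(keypoint_ed(keypoint(3, 4), keypoint(0, 0)), 5,
               ignore_attr = TRUE)
  expect_equal(keypoint_ed(keypoint(7, 7), keypoint(7, 7)), 0,
               ignore_attr = TRUE)
  d <- keypoint_ed(keypoint(10, 0), keypoint(0, 0),
                   calibrate_from_sphere(100))
  expect_equal(attr(d, "mm"), 3)
})

test_that("moment-based centroid and orientation behave as derived", {
  ln <- polyline(rbind(c(58, 64), c(198, 64)), "L1")
  hm <- encode_line(ln, c(128, 256), sigma = 6)
  lm <- line_moments(hm)
  expect_equal(unname(lm$centroid), c(128, 64), tolerance = 1e-6)
  expect_equal(lm$angle_deg, 0, tolerance = 1e-6)
  # rotating the generating line rotates the measured orientation
  tf <- compose_transform(
    compose_transform(similarity_transform(tx = 128, ty = 64),
                      similarity_transform(angle_deg = 45)),
    similarity_transform(tx = -128, ty = -64))
  hm45 <- encode_line(apply_similarity(ln, tf), c(256, 256), sigma = 6)
  expect_lt(angle_diff(line_moments(hm45)$angle_deg, 45), 0.5)
  # isotropic blob: orientation degenerate
  blob <- encode_keypoint(keypoint(64, 64), c(128, 128), sigma = 8)
  bm <- line_moments(blob)
  expect_true(bm$degenerate)
  expect_equal(bm$angle_deg, 0)
  expect_s3_class(line_moments(heatmap_grid(matrix(0, 32, 32))),
                  "kp_not_detected")
})

test_that("moment orientation recovers the generating angle over a sweep", {
  for (ang in seq(-75, 90, by = 15)) {
    d <- c(cos(ang * pi / 180), sin(ang * pi / 180))
    ln <- polyline(rbind(c(128, 128) - 80 * d, c(128, 128) + 80 * d))
    lm <- line_moments(encode_line(ln, c(256, 256), sigma = 6))
    expect_lt(angle_diff(lm$angle_deg, ang), 0.5)
  }
})

test_that("metrics are invariant under joint rigid motion", {
  set.seed(9)
  A <- matrix(runif(30, 20, 80), ncol = 2)
  B <- matrix(runif(24, 20, 80), ncol = 2)
  p <- keypoint(30, 40); g <- keypoint(55, 48)
  for (i in 1:5) {
    tf <- similarity_transform(angle_deg = runif(1, -180, 180), scale = 1,
                               tx = runif(1, -20, 20), ty = runif(1, -20, 20))
    expect_equal(assd(apply_similarity(A, tf), apply_similarity(B, tf),
                      spacing = NA),
                 assd(A, B, spacing = NA), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(keypoint_ed(apply_similarity(p, tf), apply_similarity(g, tf)),
                 keypoint_ed(p, g), tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("test-set aggregation yields medians with reproducible bootstrap CIs", {
  one <- tibble::tibble(sample = 1, metric = "ed", value = 3.2)
  r1 <- evaluate_testset(one, n_boot = 100, seed = 4)
  expect_equal(r1$median, 3.2)
  expect_equal(r1$ci_lo, 3.2)
  expect_equal(r1$ci_hi, 3.2)
  perfect <- tibble::tibble(sample = rep(1:5, 2),
                            metric = rep(c("ed", "dice"), each = 5),
                            value = rep(c(0, 1), each = 5))
  rp <- evaluate_testset(perfect, n_boot = 200, seed = 1)
  expect_equal(rp$median[rp$metric == "ed"], 0)
  expect_equal(rp$median[rp$metric == "dice"], 1)
  set.seed(31)
  dat <- tibble::tibble(sample = rep(1:40, 2),
                        metric = rep(c("a", "b"), each = 40),
                        value = c(rnorm(40, 5), c(rnorm(38, 2), NA, NA)))
  r2 <- evaluate_testset(dat, n_boot = 500, seed = 9)
  r3 <- evaluate_testset(dat, n_boot = 500, seed = 9)
  expect_identical(r2, r3)
  expect_equal(r2$cancelled[r2$metric == "b"], 2)
  expect_true(all(r2$ci_lo <= r2$median & r2$median <= r2$ci_hi))
  r4 <- evaluate_testset(dat, n_boot = 200, seed = 9,
                         cal = calibration(0.3, "manual"))
  expect_equal(r4$median_mm, r4$median * 0.3)
})
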