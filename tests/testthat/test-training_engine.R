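test_that("min-max normalization maps extremes to [0, 1] and guards constants", {
  expect_equal(normalize_intensity(matrix(c(0, 127.5, 255), 1)),
               matrix(c(0, 0.5, 1), 1))
  img <- matrix(seq(0, 1, length.out = 9), 3)
  expect_equal(normalize_intensity(img), img)
  expect_warning(z <- normalize_intensity(matrix(5, 4, 4)), "constant")
  expect_equal(z, matrix(0, 4, 4))
})

test_that("geometric preprocessing scales, pads right/bottom and inverts exactly", {
  img <- matrix(runif(512 * 384), 512, 384)  # H=512, W=384
  kp <- keypoint(100, 100, "K1")
  pp <- geometric_preprocess(img, feature_set(keypoints = list(K1 = kp)),
                             size = 256)
  expect_equal(pp$scale, 0.5)
  expect_equal(dim(pp$image), c(256, 256))
  expect_kp_equal(pp$features$keypoints$K1, keypoint(50, 50), 1e-12)
  # padded region (columns beyond 384 * 0.5 = 192) is zero
  expect_true(all(pp$image[, 195:256] == 0))
  # identity case
  img2 <- matrix(runif(256 * 256), 256, 256)
  pp2 <- geometric_preprocess(img2, size = 256)
  expect_identical(pp2$image, img2)
  # coordinate round trip through forward and inverse maps
  p <- matrix(c(123.456, 78.9), 1)
  back <- apply_similarity(apply_similarity(p, pp$transform), pp$inverse)
  expect_lt(max(abs(back - p)), 1e-9)
})

test_that("augmentation maps geometry by the exact affine it applies to the raster", {
  img <- matrix(runif(64 * 64), 64, 64)
  fs <- feature_set(keypoints = list(K1 = keypoint(20, 30, "K1")))
  # forced flip only
  set.seed(1)
  a <- augment_sample(list(image = img, features = fs), flip_prob = 1,
                      shear_prob = 0, rotation_range = c(0, 0),
                      scale_range = c(1, 1))
  expect_kp_equal(a$features$keypoints$K1, keypoint(63 - 20, 30), 1e-9)
  # identity draw leaves geometry unchanged
  b <- augment_sample(list(image = img, features = fs), flip_prob = 0,
                      shear_prob = 0, rotation_range = c(0, 0),
                      scale_range = c(1, 1))
  expect_kp_equal(b$features$keypoints$K1, fs$keypoints$K1, 1e-9)
  expect_lt(max(abs(b$image - img)), 1e-9)
  # +45 then -45 degree rotation about the center restores coordinates
  r1 <- augment_sample(list(image = img, features = fs), flip_prob = 0,
                       shear_prob = 0, rotation_range = c(45, 45),
                       scale_range = c(1, 1))
  r2 <- augment_sample(list(image = r1$image, features = r1$features),
                       flip_prob = 0, shear_prob = 0,
                       rotation_range = c(-45, -45), scale_range = c(1, 1))
  expect_kp_equal(r2$features$keypoints$K1, fs$keypoints$K1, 1e-6)
})

test_that("task losses match their closed forms", {
  kpt <- task_spec("kpt", "keypoint", "K1")
  seg <- task_spec("seg", "segmentation", "S1")
  h <- matrix(runif(100), 10)
  expect_equal(task_loss(kpt, h, h), 0)
  ones <- matrix(1, 100, 100)
  expect_lt(task_loss(seg, ones * 0.999999, ones), 1e-3)
  half <- matrix(0.5, 100, 100)
  # BCE = ln 2; soft-Dice term = 1 - (2*0.5*1e4 + 1)/(0.5e4 + 1e4 + 1)
  expect_equal(task_loss(seg, half, ones),
               log(2) + 1 - (2 * 0.5 * 1e4 + 1) / (1.5e4 + 1),
               tolerance = 1e-9)
  expect_equal(task_loss(seg, half, ones), log(2) + 1 / 3, tolerance = 1e-4)
  expect_error(task_loss(kpt, matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("all-zero heatmap prediction loss equals the mean squared target", {
  kpt <- task_spec("kpt", "keypoint", "K1")
  tg <- unclass(encode_keypoint(keypoint(30, 30), c(64, 64), 4))
  expect_equal(task_loss(kpt, tg * 0, tg), mean(tg^2))
})

test_that("composite loss is the weighted sum and demands full weights", {
  l <- c(seg = 1, kpt = 2, lin = 3)
  expect_equal(composite_loss(l, c(seg = 1, kpt = 1, lin = 1)), 6)
  expect_equal(composite_loss(c(a = 1, b = 2), c(a = 2, b = 0.5)), 3)
  expect_equal(composite_loss(c(a = 4), c(a = 0.25)), 1)
  expect_error(composite_loss(l, c(seg = 1, kpt = 1)), "missing weight")
})

test_that("GradNorm updates keep the weight simplex and its symmetries", {
  # T = 1 degenerates to the single-task case
  w1 <- gradnorm_step(c(a = 1), c(a = 0.5), c(a = 1), c(a = 2))
  expect_equal(w1, c(a = 1))
  # identical tasks keep identical weights
  w <- c(a = 1, b = 1)
  for (i in 1:20) {
    w <- gradnorm_step(w, c(a = 0.4, b = 0.4), c(a = 1, b = 1),
                       c(a = 3 * w[["a"]], b = 3 * w[["b"]]))
    expect_equal(w[["a"]], w[["b"]])
    expect_equal(sum(w), 2)
  }
  # asymmetric tasks: renormalization invariant holds along the trajectory
  w <- c(a = 1, b = 1, c = 1)
  set.seed(2)
  for (i in 1:30) {
    g <- c(a = runif(1, 1, 5), b = runif(1, 0.1, 0.5), c = runif(1, 0.5, 2))
    w <- gradnorm_step(w, c(a = 0.9, b = 0.3, c = 0.6),
                       c(a = 1, b = 1, c = 1), g * w)
    expect_equal(sum(w), 3, tolerance = 1e-12)
    expect_true(all(w > 0))
  }
  expect_warning(w2 <- gradnorm_step(c(a = 1, b = 1), c(a = 1, b = 1),
                                     c(a = 1, b = 1), c(a = NaN, b = 1)),
                 "non-finite")
  expect_equal(w2, c(a = 1, b = 1))
})

test_that("cyclical schedule hits the printed bounds with inverse momentum phase", {
  cfg <- train_config()
  s0 <- clr_schedule(0, cfg)
  expect_equal(s0$lr, 0.001)
  expect_equal(s0$momentum, 0.9)
  s180 <- clr_schedule(180, cfg)
  expect_equal(s180$lr, 0.1)
  expect_equal(s180$momentum, 0.8)
  s360 <- clr_schedule(360, cfg)
  expect_equal(s360$lr, 0.001)
  expect_equal(s360$momentum, 0.9)
  s90 <- clr_schedule(90, cfg)
  expect_equal(s90$lr, 0.001 + 0.5 * (0.1 - 0.001))
  expect_equal(s90$momentum, 0.9 - 0.5 * 0.1)
  # periodicity
  expect_equal(clr_schedule(725, cfg), clr_schedule(5, cfg))
})

test_that("training selects the epoch minimizing unweighted validation loss, reproducibly", {
  pcfg <- phantom_config(image_size = c(32, 32), seed = 19)
  ds <- phantom_dataset(pcfg, 10, split = c(0.6, 0.4, 0))
  tasks <- list(task_spec("seg", "segmentation", c("S1", "S2")),
                task_spec("kpt", "keypoint", c("K1", "K4")))
  mcfg <- model_config(tasks, "multi_head", n_features = 8, depth = 2,
                       input_size = 32)
  tcfg <- train_config(epochs = 3, sigma = 2, seed = 3, cycle_len = 24)
  fit1 <- train(build_model(mcfg, seed = 1), ds, tcfg)
  totals <- tapply(fit1$history$val_loss, fit1$history$epoch, sum)
  expect_equal(fit1$best_epoch, unname(which.min(totals)))
  expect_equal(fit1$best_val_loss, unname(min(totals)))
  fit2 <- train(build_model(mcfg, seed = 1), ds, tcfg)
  expect_equal(fit1$history, fit2$history)
  expect_error(train(build_model(mcfg), list(samples = list(),
                                             train = integer(0),
                                             val = integer(0)), tcfg),
               "empty")
  # broom-style accessors
  expect_identical(tidy(fit1), fit1$history)
  expect_equal(glance(fit1)$best_epoch, fit1$best_epoch)
})

test_that("uniform weighting makes the composite equal the selection criterion", {
  l <- c(seg = 0.7, kpt = 0.1, lin = 0.3)
  w <- stats::setNames(rep(1, 3), names(l))
  expect_equal(composite_loss(l, w), sum(l))
})
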