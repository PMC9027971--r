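test_that("phantom generation is deterministic in (seed, index)", {
  cfg <- small_phantom_cfg(seed = 5)
  a <- generate_phantom(cfg, 3)
  b <- generate_phantom(cfg, 3)
  expect_identical(a$image, b$image)
  expect_identical(a$keypoints, b$keypoints)
  expect_identical(a$plan_truth, b$plan_truth)
  c <- generate_phantom(cfg, 4)
  expect_false(identical(a$image, c$image))
  # generation does not disturb the caller's RNG stream
  set.seed(1); r1 <- runif(1)
  set.seed(1); invisible(generate_phantom(cfg, 9)); r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("femur and tibia masks overlap at the joint (multi-label)", {
  cfg <- small_phantom_cfg(seed = 8)
  found <- FALSE
  for (i in 1:6) {
    ph <- generate_phantom(cfg, i)
    mk <- rasterize_mask(ph$regions, dim(ph$image))
    ov <- sum(mk$channels$S1 * mk$channels$S2)
    if (ov > 0) found <- TRUE
  }
  expect_true(found)
})

test_that("stored plan truth equals re-running the blueprints on ground truth", {
  cfg <- small_phantom_cfg(seed = 13)
  for (i in 1:4) {
    ph <- generate_phantom(cfg, i)
    expect_identical(ph$plan_truth$MPFL,
                     plan_mpfl(ph$features, cal = ph$calibration))
    expect_identical(ph$plan_truth$ACL_femur, plan_acl_femur(ph$features))
    expect_identical(ph$plan_truth$ACL_tibia, plan_acl_tibia(ph$features))
    expect_identical(ph$plan_truth$PCL,
                     plan_pcl(ph$features, cal = ph$calibration))
    expect_equal(ph$plan_truth$MPFL$status, "ok")
  }
})

test_that("phantom keypoints lie on the generating contours or lines", {
  cfg <- small_phantom_cfg(seed = 21)
  for (i in 1:4) {
    ph <- generate_phantom(cfg, i)
    ring1 <- resample_ring(ph$regions$S1$outer, 0.25)
    ring2 <- resample_ring(ph$regions$S2$outer, 0.25)
    d_to <- function(kp, pts) {
      min(sqrt((pts[, 1] - kp$x)^2 + (pts[, 2] - kp$y)^2))
    }
    # K3/K7 on the femoral outline; K4/K5/K6 on the tibial outline
    for (k in c("K3", "K7")) expect_lt(d_to(ph$keypoints[[k]], ring1), 0.5)
    for (k in c("K4", "K5", "K6")) expect_lt(d_to(ph$keypoints[[k]], ring2), 0.5)
    # K1/K2 are the endpoints of the intercondylar line L1
    expect_lt(d_to(ph$keypoints$K1, ph$lines$L1$points[1, , drop = FALSE]),
              1e-9)
    expect_lt(d_to(ph$keypoints$K2, ph$lines$L1$points[2, , drop = FALSE]),
              1e-9)
  }
})

test_that("ground-truth features survive the encode/decode round trip", {
  cfg <- small_phantom_cfg(seed = 33, size = 128)
  ph <- generate_phantom(cfg, 2)
  for (kp in ph$keypoints) {
    hm <- encode_keypoint(kp, dim(ph$image), sigma = 6)
    am <- decode_keypoint_argmax(hm)
    expect_lte(abs(am$x - kp$x), 0.5)
    expect_lte(abs(am$y - kp$y), 0.5)
    ft <- decode_keypoint_fit(hm)
    expect_lt(keypoint_ed(ft, kp), 0.1)
  }
})

test_that("intraoperative preset raises artifact rates", {
  cfg <- phantom_config(preset = "intraoperative")
  expect_gt(cfg$implant_prob, phantom_config()$implant_prob)
  expect_gt(cfg$truncation_prob, phantom_config()$truncation_prob)
  expect_gt(cfg$bilateral_prob, phantom_config()$bilateral_prob)
  expect_error(phantom_config(condyle_radius = c(5, 2)), "invalid range")
  expect_error(phantom_config(implant_prob = 1.4), "implant_prob")
})

test_that("dataset writer produces a disjoint split and reproducible manifest", {
  dir <- withr::local_tempdir()
  cfg <- phantom_config(image_size = c(48, 48), seed = 3)
  man <- generate_dataset(cfg, 10, split = c(0.6, 0.2, 0.2), dir)
  expect_equal(as.vector(table(man$split)[c("train", "val", "test")]),
               c(6, 2, 2))
  expect_equal(anyDuplicated(man$index), 0)
  expect_true(all(file.exists(file.path(dir, man$image))))
  expect_true(all(file.exists(file.path(dir, man$annotation))))
  ann <- read_annotation(file.path(dir, man$annotation[1]))
  expect_length(ann$features$keypoints, 7)
  expect_length(ann$features$lines, 3)
  expect_length(ann$features$regions, 2)
  # regeneration is byte-identical
  dir2 <- withr::local_tempdir()
  generate_dataset(cfg, 10, split = c(0.6, 0.2, 0.2), dir2)
  expect_identical(readLines(file.path(dir, "manifest.csv")),
                   readLines(file.path(dir2, "manifest.csv")))
  expect_identical(readLines(file.path(dir, man$annotation[5])),
                   readLines(file.path(dir2, man$annotation[5])))
  expect_error(generate_dataset(cfg, 4, split = c(0.98, 0.01, 0.01), dir),
               "impossible split")
})
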