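mpfl_features <- function(kp_a = c(140, 80), kp_b = c(140, 160),
                          cortex = rbind(c(100, 20), c(100, 220))) {
  feature_set(
    keypoints = list(K3 = keypoint(kp_a[1], kp_a[2], "K3"),
                     K7 = keypoint(kp_b[1], kp_b[2], "K7")),
    lines = list(L2 = polyline(cortex, "L2")))
}

test_that("MPFL target is the midpoint of the perpendicular feet on the cortex line", {
  plan <- plan_mpfl(mpfl_features())
  expect_equal(plan$status, "ok")
  expect_kp_equal(plan$targets$insertion, keypoint(100, 120), 1e-9)
  expect_kp_equal(plan$intermediates$foot_a, keypoint(100, 80), 1e-9)
  expect_kp_equal(plan$intermediates$foot_b, keypoint(100, 160), 1e-9)
  # missing cortex subsection cancels, never crashes
  noline <- feature_set(keypoints = mpfl_features()$keypoints)
  expect_equal(plan_mpfl(noline)$status, "cancelled")
  co <- mpfl_features(kp_a = c(140, 80), kp_b = c(140, 80))
  expect_equal(plan_mpfl(co)$status, "cancelled")
  expect_match(plan_mpfl(co)$reason, "degenerate")
})

test_that("MPFL tolerance circle and anterior offset require calibration", {
  cal <- calibration(0.5, "manual")
  p <- plan_mpfl(mpfl_features(), cal = cal)
  expect_equal(p$intermediates$tolerance_radius_px, 2.5 / 0.5)
  bp <- blueprint("MPFL", constants = list(anterior_offset_mm = 5))
  p2 <- plan_mpfl(mpfl_features(), bp, cal = cal)
  # keypoints lie at x = 140 > 100: anterior offset moves toward them
  expect_kp_equal(p2$targets$insertion, keypoint(110, 120), 1e-9)
  expect_equal(plan_mpfl(mpfl_features(), bp)$status, "cancelled")
})

acl_femur_features <- function() {
  ring <- rbind(c(100, 100), c(180, 100), c(180, 160), c(100, 160))
  feature_set(
    keypoints = list(K1 = keypoint(110, 110, "K1"),
                     K2 = keypoint(170, 110, "K2")),
    regions = list(S1 = polygon_region(ring, label = "S1")))
}

test_that("ACL femoral targets sit at fractional quadrant-frame coordinates", {
  bp <- blueprint("ACL_femur", constants = list(t_u_am = 0.25, t_v_am = 0.25,
                                                t_u_pl = 0.5, t_v_pl = 0.75))
  p <- plan_acl_femur(acl_femur_features(), bp)
  expect_equal(p$status, "ok")
  # frame: u along +x from x=100..180, v = +y (condyle centroid below K1)
  expect_kp_equal(p$targets$am, keypoint(100 + 0.25 * 80, 100 + 0.25 * 60),
                  1e-9)
  expect_kp_equal(p$targets$pl, keypoint(100 + 0.5 * 80, 100 + 0.75 * 60),
                  1e-9)
  expect_error(blueprint("ACL_femur", constants = list(t_u_am = 1.2)),
               "\\[0, 1\\]")
  noreg <- feature_set(keypoints = acl_femur_features()$keypoints)
  expect_equal(plan_acl_femur(noreg)$status, "cancelled")
})

test_that("ACL tibial targets interpolate the AP diameter", {
  fs <- feature_set(keypoints = list(K4 = keypoint(0, 0, "K4"),
                                     K5 = keypoint(100, 0, "K5")))
  bp <- blueprint("ACL_tibia", constants = list(t_am = 0.3, t_pl = 0.55))
  p <- plan_acl_tibia(fs, bp)
  expect_kp_equal(p$targets$am, keypoint(30, 0), 1e-9)
  expect_kp_equal(p$targets$pl, keypoint(55, 0), 1e-9)
  b0 <- blueprint("ACL_tibia", constants = list(t_am = 0, t_pl = 1))
  p0 <- plan_acl_tibia(fs, b0)
  expect_kp_equal(p0$targets$am, keypoint(0, 0), 1e-12)
  expect_kp_equal(p0$targets$pl, keypoint(100, 0), 1e-12)
  co <- feature_set(keypoints = list(K4 = keypoint(5, 5, "K4"),
                                     K5 = keypoint(5, 5, "K5")))
  expect_equal(plan_acl_tibia(co)$status, "cancelled")
})

pcl_features <- function() {
  feature_set(keypoints = list(K6 = keypoint(200, 300, "K6")),
              lines = list(L3 = polyline(rbind(c(150, 300), c(260, 300)),
                                         "L3")))
}

test_that("PCL plan converts metric offsets and refuses to run uncalibrated", {
  cal <- calibration(0.5, "sphere")
  bp <- blueprint("PCL", constants = list(offset_mm = 10, wire_angle_deg = 0))
  p <- plan_pcl(pcl_features(), bp, cal)
  expect_equal(p$status, "ok")
  # axis is horizontal; distal orientation is ambiguous for y-constant
  # lines, offset magnitude must still be 10 mm = 20 px along the axis
  expect_equal(abs(p$targets$insertion$x - 200), 20, tolerance = 1e-9)
  expect_equal(p$targets$insertion$y, 300, tolerance = 1e-9)
  # wire angle 0: guidewire parallel to the reference line
  wd <- diff(p$targets$guidewire$points)
  expect_lt(angle_diff(atan2(wd[2], wd[1]) * 180 / pi, 0), 1e-9)
  expect_equal(plan_pcl(pcl_features(), bp, NULL)$status, "cancelled")
  expect_match(plan_pcl(pcl_features(), bp,
                        calibration(NA, "none"))$reason, "no-scale")
})

test_that("every plan op is similarity-equivariant on randomized instances", {
  set.seed(23)
  cal <- calibration(0.4, "sphere")
  for (i in 1:100) {
    tf <- similarity_transform(angle_deg = runif(1, -180, 180), scale = 1,
                               tx = runif(1, -40, 40), ty = runif(1, -40, 40))
    # MPFL
    fs <- mpfl_features(kp_a = runif(2, 60, 200), kp_b = runif(2, 60, 200),
                        cortex = matrix(runif(4, 10, 250), 2))
    p0 <- plan_mpfl(fs)
    p1 <- plan_mpfl(map_features_test(fs, tf))
    if (p0$status == "ok") {
      expect_kp_equal(p1$targets$insertion,
                      apply_similarity(p0$targets$insertion, tf), 1e-6)
    }
    # ACL tibia with random endpoints and scale change
    tfs <- similarity_transform(angle_deg = runif(1, -90, 90),
                                scale = runif(1, 0.5, 2),
                                tx = runif(1, -20, 20), ty = runif(1, -20, 20))
    ft <- feature_set(keypoints = list(
      K4 = keypoint(runif(1, 0, 100), runif(1, 0, 100), "K4"),
      K5 = keypoint(runif(1, 100, 200), runif(1, 100, 200), "K5")))
    q0 <- plan_acl_tibia(ft)
    q1 <- plan_acl_tibia(map_features_test(ft, tfs))
    expect_kp_equal(q1$targets$am, apply_similarity(q0$targets$am, tfs), 1e-6)
    expect_kp_equal(q1$targets$pl, apply_similarity(q0$targets$pl, tfs), 1e-6)
  }
  # ACL femur under a fixed 37-degree rotation
  tf37 <- similarity_transform(angle_deg = 37, tx = 11, ty = -7)
  f0 <- plan_acl_femur(acl_femur_features())
  f1 <- plan_acl_femur(map_features_test(acl_femur_features(), tf37))
  expect_kp_equal(f1$targets$am, apply_similarity(f0$targets$am, tf37), 1e-6)
  expect_kp_equal(f1$targets$pl, apply_similarity(f0$targets$pl, tf37), 1e-6)
  # PCL under rigid motion (calibration is metric, scale fixed to 1);
  # a sloped axis keeps the distal orientation rule unambiguous
  pf <- feature_set(keypoints = list(K6 = keypoint(200, 300, "K6")),
                    lines = list(L3 = polyline(rbind(c(150, 280),
                                                     c(260, 330)), "L3")))
  tfr <- similarity_transform(angle_deg = 63, tx = 5, ty = 9)
  g0 <- plan_pcl(pf, cal = cal)
  g1 <- plan_pcl(map_features_test(pf, tfr), cal = cal)
  expect_kp_equal(g1$targets$insertion,
                  apply_similarity(g0$targets$insertion, tfr), 1e-6)
})

test_that("plan re-execution is pure and respects the dependency graph", {
  fs <- feature_set(keypoints = list(
    K1 = keypoint(110, 110, "K1"), K2 = keypoint(170, 110, "K2"),
    K4 = keypoint(90, 150, "K4"), K5 = keypoint(180, 150, "K5")))
  bp <- blueprint("ACL_tibia")
  p0 <- execute_plan(fs, bp)
  expect_identical(p0, plan_acl_tibia(fs, bp))
  e1 <- execute_plan(fs, bp,
                     edits = list(kp_anterior = keypoint(80, 150)))
  e2 <- execute_plan(fs, bp,
                     edits = list(kp_anterior = keypoint(80, 150)))
  expect_identical(e1, e2)
  expect_false(identical(e1$targets$am, p0$targets$am))
  expect_error(execute_plan(fs, bp, edits = list(volume = keypoint(1, 1))),
               "unknown blueprint role")
  # editing a tibial endpoint leaves an independent femoral plan untouched
  ff <- acl_femur_features()
  bf <- blueprint("ACL_femur")
  f0 <- execute_plan(ff, bf)
  ff2 <- ff
  ff2$keypoints$K4 <- keypoint(1, 1, "K4")
  expect_identical(execute_plan(ff2, bf)$targets, f0$targets)
})
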