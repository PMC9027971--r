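test_that("argmax decoding round-trips integer keypoints and breaks ties deterministically", {
  hm <- encode_keypoint(keypoint(120, 77), c(256, 256))
  d <- decode_keypoint_argmax(hm)
  expect_equal(c(d$x, d$y), c(120, 77))
  expect_equal(d$confidence, 1)
  expect_s3_class(decode_keypoint_argmax(heatmap_grid(matrix(0, 32, 32))),
                  "kp_not_detected")
  m <- matrix(0, 32, 32)
  m[6, 6] <- 0.7; m[6, 10] <- 0.7  # equal maxima at (5,5) and (9,5)
  d2 <- decode_keypoint_argmax(heatmap_grid(m))
  expect_equal(c(d2$x, d2$y), c(5, 5))
})

test_that("Gaussian least-squares decoding recovers sub-pixel centers", {
  true <- keypoint(120.4, 77.6)
  hm <- encode_keypoint(true, c(256, 256), sigma = 6)
  fit <- decode_keypoint_fit(hm)
  expect_lt(keypoint_ed(fit, true), 0.05)
  am <- decode_keypoint_argmax(hm)
  expect_lt(keypoint_ed(fit, true), keypoint_ed(am, true))
  expect_gt(keypoint_ed(am, true), 0.1)  # argmax is pixel-quantized here
  flat <- heatmap_grid(matrix(0.5, 64, 64), sigma = 6)
  ft <- decode_keypoint_fit(flat)  # flat window: falls back to argmax path
  expect_equal(c(ft$x, ft$y), c(0, 0))
})

test_that("line decoding recovers orientation across angles and handles vertical lines", {
  for (ang in seq(-80, 90, by = 34)) {
    d <- unitv_test(ang)
    ctr <- c(128, 128)
    ln <- polyline(rbind(ctr - 70 * d, ctr + 70 * d), "L1")
    hm <- encode_line(ln, c(256, 256), sigma = 6)
    pl <- decode_line(hm)
    expect_true(is_detected(pl))
    fit <- stats::prcomp(pl$points)$rotation[, 1]
    got <- atan2(fit[2], fit[1]) * 180 / pi
    expect_lt(angle_diff(got, ang), 0.5)
  }
  vert <- decode_line(encode_line(polyline(rbind(c(100, 30), c(100, 220))),
                                  c(256, 256)))
  expect_true(is_detected(vert))
  expect_lt(diff(range(vert$points[, 1])), 1)
  expect_s3_class(decode_line(heatmap_grid(matrix(0, 64, 64))),
                  "kp_not_detected")
})

test_that("line decoding is invariant to positive rescaling of the heatmap", {
  ln <- polyline(rbind(c(40, 60), c(200, 170)), "L1")
  hm <- encode_line(ln, c(256, 256), sigma = 6)
  p1 <- decode_line(hm, threshold = 0.3)
  hm2 <- heatmap_grid(unclass(hm) * 0.8, sigma = 6, kind = "line")
  p2 <- decode_line(hm2, threshold = 0.3 * 0.8)
  a1 <- stats::prcomp(p1$points)$rotation[, 1]
  a2 <- stats::prcomp(p2$points)$rotation[, 1]
  expect_lt(angle_diff(atan2(a1[2], a1[1]) * 180 / pi,
                       atan2(a2[2], a2[1]) * 180 / pi), 0.5)
  expect_lt(max(abs(colMeans(p1$points) - colMeans(p2$points))), 1)
})

test_that("mask-to-polygon extraction traces, filters and flags components", {
  ch <- matrix(0, 64, 64)
  ch[11:30, 11:30] <- 1  # 20x20 block
  mk <- structure(list(channels = list(S1 = ch), shape = c(64, 64)),
                  class = "kp_mask")
  polys <- mask_to_polygons(mk)
  expect_s3_class(polys$S1, "kp_polygon")
  expect_equal(abs(shoelace_area(polys$S1$outer)), 400, tolerance = 0.01)
  expect_false(attr(polys$S1, "fragmented"))
  # small second blob is dropped silently
  ch2 <- ch; ch2[50:51, 50:52] <- 1
  mk$channels$S1 <- ch2
  p2 <- mask_to_polygons(mk, min_area_frac = 0.05)
  expect_false(attr(p2$S1, "fragmented"))
  expect_equal(abs(shoelace_area(p2$S1$outer)), 400, tolerance = 0.01)
  # comparable second blob raises the fragmentation flag
  ch3 <- ch; ch3[40:57, 40:57] <- 1
  mk$channels$S1 <- ch3
  p3 <- mask_to_polygons(mk)
  expect_true(attr(p3$S1, "fragmented"))
  mk$channels$S1 <- matrix(0, 64, 64)
  expect_s3_class(mask_to_polygons(mk)$S1, "kp_not_detected")
})

test_that("rasterize/trace round trip preserves convex polygon area within 2%", {
  set.seed(11)
  for (i in 1:5) {
    ctr <- runif(2, 100, 150)
    r <- runif(1, 40, 80)
    th <- seq(0, 2 * pi, length.out = 41)[-41]
    ring <- cbind(ctr[1] + r * cos(th), ctr[2] + (0.6 + 0.4 * runif(1)) * r * sin(th))
    rg <- polygon_region(ring, label = "S1")
    mk <- rasterize_mask(list(rg), c(256, 256))
    back <- mask_to_polygons(mk)$S1
    a0 <- abs(shoelace_area(rg$outer))
    a1 <- abs(shoelace_area(back$outer))
    expect_lt(abs(a1 - a0) / a0, 0.02)
  }
})

test_that("contour subsections follow the weighting heatmap", {
  rg <- square_region(49.5, 49.5, 100)
  uniform <- heatmap_grid(matrix(1, 256, 256), kind = "line")
  full <- contour_subsection(rg, uniform)
  expect_true(is_detected(full))
  ring_len <- 4 * 100
  seg_len <- sum(sqrt(rowSums(diff(full$points)^2)))
  expect_equal(seg_len, ring_len, tolerance = 0.02)
  # weight supported on the left half-plane keeps only x < 100 points
  wl <- matrix(0, 256, 256); wl[, 1:100] <- 1
  left <- contour_subsection(rg, heatmap_grid(wl, kind = "line"))
  expect_true(is_detected(left))
  expect_true(all(left$points[, 1] <= 100))
  expect_s3_class(contour_subsection(rg, heatmap_grid(matrix(0, 256, 256))),
                  "kp_not_detected")
})
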