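# Shared fixtures: all built in code at test time.

# Axis-aligned square polygon with half-integer bounds so every pixel
# center is unambiguously inside or outside.
square_region <- function(x0, y0, side, label = "S1") {
  polygon_region(rbind(c(x0, y0), c(x0 + side, y0),
                       c(x0 + side, y0 + side), c(x0, y0 + side)),
                 label = label)
}

random_similarity <- function() {
  similarity_transform(angle_deg = runif(1, -180, 180),
                       scale = runif(1, 0.5, 2),
                       tx = runif(1, -50, 50), ty = runif(1, -50, 50))
}

small_phantom_cfg <- function(seed = 42, size = 96) {
  phantom_config(image_size = c(size, size), seed = seed)
}

expect_kp_equal <- function(a, b, tol = 1e-6) {
  expect_lt(sqrt((a$x - b$x)^2 + (a$y - b$y)^2), tol)
}

unitv_test <- function(deg) c(cos(deg * pi / 180), sin(deg * pi / 180))

map_features_test <- function(fs, tf) {
  mp <- function(l) lapply(l, function(f) apply_similarity(f, tf))
  feature_set(keypoints = mp(fs$keypoints), lines = mp(fs$lines),
              regions = mp(fs$regions))
}
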