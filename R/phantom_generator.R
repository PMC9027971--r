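# Synthetic lateral knee phantoms with exact analytic ground truth.
#
# The phantom is schematic rather than anatomically realistic: it
# reproduces the structural traits that the detection and planning stages
# consume — smooth bone outlines with landmarks lying on them, a visible
# intercondylar (Blumensaat-like) ridge, femorotibial overlap under the
# additive transmissive intensity model, shaft truncation, implant-like
# high-intensity overlays, bilateral exposure, and a stored pixel-to-mm
# calibration emulating the reference-sphere pathway. All ground truth
# (S1/S2 polygons, keypoints K1-K7, lines L1-L3, per-application plans) is
# computed from the generating parameters; no annotation step exists.

#' Phantom generator configuration
#'
#' Anatomy ranges are expressed at a 256 px reference frame and scaled to
#' `image_size`. The `intraoperative` preset raises implant overlap, shaft
#' truncation and bilateral exposure rates and noise, mirroring mobile
#' C-arm acquisitions; `diagnostic` mirrors standardized radiographs.
#'
#' @param image_size Integer `(H, W)` (default `c(256, 256)`).
#' @param seed Base RNG seed; each sample is deterministic in
#'   `(seed, index)`.
#' @param preset `"diagnostic"` or `"intraoperative"`.
#' @param condyle_radius,shaft_width_femur,shaft_length_femur,
#'   plateau_halfwidth,plateau_thickness,shaft_width_tibia,
#'   shaft_length_tibia 2-vectors giving uniform ranges in reference px.
#' @param rotation_deg,scale,translate_px Pose ranges (uniform).
#' @param implant_prob,truncation_prob,bilateral_prob Artifact rates.
#' @param noise_sd Additive Gaussian noise level (pre-normalization).
#' @param mm_per_px_range Range of the stored synthetic calibration.
#' @return A `kp_phantom_config`.
#' @export
phantom_config <- function(image_size = c(256, 256), seed = 1,
                           preset = c("diagnostic", "intraoperative"),
                           condyle_radius = c(30, 40),
                           shaft_width_femur = c(22, 30),
                           shaft_length_femur = c(80, 115),
                           plateau_halfwidth = c(40, 52),
                           plateau_thickness = c(12, 18),
                           shaft_width_tibia = c(20, 28),
                           shaft_length_tibia = c(75, 105),
                           rotation_deg = NULL, scale = c(0.9, 1.1),
                           translate_px = c(-10, 10),
                           implant_prob = NULL, truncation_prob = NULL,
                           bilateral_prob = NULL, noise_sd = NULL,
                           mm_per_px_range = c(0.2, 0.5)) {
  preset <- match.arg(preset)
  intra <- preset == "intraoperative"
  if (is.null(rotation_deg)) rotation_deg <- if (intra) c(-25, 25) else c(-15, 15)
  if (is.null(implant_prob)) implant_prob <- if (intra) 0.8 else 0.25
  if (is.null(truncation_prob)) truncation_prob <- if (intra) 0.7 else 0.2
  if (is.null(bilateral_prob)) bilateral_prob <- if (intra) 0.3 else 0.02
  if (is.null(noise_sd)) noise_sd <- if (intra) 0.04 else 0.02
  cfg <- list(image_size = as.integer(image_size), seed = as.integer(seed),
              preset = preset, condyle_radius = condyle_radius,
              shaft_width_femur = shaft_width_femur,
              shaft_length_femur = shaft_length_femur,
              plateau_halfwidth = plateau_halfwidth,
              plateau_thickness = plateau_thickness,
              shaft_width_tibia = shaft_width_tibia,
              shaft_length_tibia = shaft_length_tibia,
              rotation_deg = rotation_deg, scale = scale,
              translate_px = translate_px, implant_prob = implant_prob,
              truncation_prob = truncation_prob,
              bilateral_prob = bilateral_prob, noise_sd = noise_sd,
              mm_per_px_range = mm_per_px_range)
  for (nm in c("condyle_radius", "shaft_width_femur", "shaft_length_femur",
               "plateau_halfwidth", "plateau_thickness", "shaft_width_tibia",
               "shaft_length_tibia", "scale")) {
    rg <- cfg[[nm]]
    if (length(rg) != 2 || rg[1] > rg[2] || rg[1] <= 0) {
      stop("invalid range for ", nm)
    }
  }
  for (nm in c("implant_prob", "truncation_prob", "bilateral_prob")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) stop(nm, " must be in [0, 1]")
  }
  structure(cfg, class = "kp_phantom_config")
}

phantom_seed <- function(cfg, index) {
  as.integer((as.numeric(cfg$seed) * 1000003 + as.numeric(index)) %%
               2147483629)
}

runif1 <- function(rg) runif(1, rg[1], rg[2])

#' Generate one synthetic knee phantom
#'
#' Deterministic in `(cfg$seed, index)`. The femur is built from a condyle
#' disc merged with a shaft capsule, the tibia from a plateau block with a
#' shaft; both are posed by a random similarity. The image is the sum of
#' per-structure attenuation fields (plus optional implant overlays,
#' bilateral ghost anatomy and Gaussian noise), min-max normalized.
#'
#' @param cfg A [phantom_config()].
#' @param index Sample index (>= 1).
#' @return A `kp_phantom`: list with `image` (H x W in `[0, 1]`),
#'   `regions`, `keypoints`, `lines` (feature lists), `features`
#'   (a [feature_set()]), `plan_truth` (per-application `kp_plan`),
#'   `calibration`, and `params`.
#' @export
generate_phantom <- function(cfg, index = 1) {
  with_local_seed(phantom_seed(cfg, index), generate_phantom_impl(cfg, index))
}

generate_phantom_impl <- function(cfg, index) {
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  u <- min(H, W) / 256  # anatomy ranges are given at a 256 px reference
  for (attempt in 1:25) {
    par <- draw_phantom_params(cfg)
    geo <- phantom_geometry(par, u, H, W)
    if (phantom_in_frame(geo, H, W)) break
    geo <- NULL
  }
  if (is.null(geo)) stop("could not pose phantom inside the frame")
  img <- render_phantom(geo, par, cfg, H, W)
  cal <- calibration(par$mm_per_px, "sphere")
  features <- feature_set(keypoints = geo$keypoints, lines = geo$lines,
                          regions = geo$regions,
                          provenance = stats::setNames(
                            rep("ground_truth", 12),
                            c(paste0("K", 1:7), paste0("L", 1:3), "S1", "S2")))
  plan_truth <- list(
    MPFL = plan_mpfl(features, blueprint("MPFL"), cal),
    ACL_femur = plan_acl_femur(features, blueprint("ACL_femur")),
    ACL_tibia = plan_acl_tibia(features, blueprint("ACL_tibia")),
    PCL = plan_pcl(features, blueprint("PCL"), cal))
  structure(list(image = img, regions = geo$regions,
                 keypoints = geo$keypoints, lines = geo$lines,
                 features = features, plan_truth = plan_truth,
                 calibration = cal, params = par, index = index),
            class = "kp_phantom")
}

draw_phantom_params <- function(cfg) {
  truncated <- runif(1) < cfg$truncation_prob
  list(
    r_c = runif1(cfg$condyle_radius),
    w_f = runif1(cfg$shaft_width_femur),
    L_f = runif1(cfg$shaft_length_femur) * if (truncated) 0.55 else 1,
    R_ap = runif1(cfg$plateau_halfwidth),
    h_p = runif1(cfg$plateau_thickness),
    w_t = runif1(cfg$shaft_width_tibia),
    L_t = runif1(cfg$shaft_length_tibia) * if (truncated) 0.55 else 1,
    femur_tilt = runif(1, -8, 8),      # shaft direction jitter, degrees
    tibia_tilt = runif(1, -8, 8),
    overlap = runif(1, 2, 8),          # femorotibial superimposition, px
    pose_rot = runif1(cfg$rotation_deg),
    pose_scale = runif1(cfg$scale),
    pose_tx = runif1(cfg$translate_px),
    pose_ty = runif1(cfg$translate_px),
    truncated = truncated,
    implant = runif(1) < cfg$implant_prob,
    bilateral = runif(1) < cfg$bilateral_prob,
    mm_per_px = runif1(cfg$mm_per_px_range),
    noise_sd = cfg$noise_sd)
}

unitv <- function(deg) c(cos(deg * pi / 180), sin(deg * pi / 180))

phantom_geometry <- function(par, u, H, W) {
  ctr <- c((W - 1) / 2, (H - 1) / 2)
  pose <- compose_transform(
    similarity_transform(tx = ctr[1] + par$pose_tx * u,
                         ty = ctr[2] + par$pose_ty * u),
    similarity_transform(angle_deg = par$pose_rot,
                         scale = par$pose_scale * u))
  # --- femur in canonical (256-reference) frame, joint near the origin ---
  r <- par$r_c
  C <- c(-6, -28)                       # condyle disc center
  a <- unitv(-90 + par$femur_tilt)      # shaft direction, proximal (up)
  n <- c(-a[2], a[1])                   # posterior normal
  if (n[1] < 0) n <- -n
  s <- sqrt(r^2 - (par$w_f / 2)^2)
  L <- s + par$L_f
  P1 <- C + (par$w_f / 2) * n + s * a
  P2 <- C + (par$w_f / 2) * n + L * a
  P3 <- C - (par$w_f / 2) * n + L * a
  P4 <- C - (par$w_f / 2) * n + s * a
  ang <- function(p) atan2(p[2] - C[2], p[1] - C[1])
  a4 <- ang(P4); a1 <- ang(P1); aA <- atan2(a[2], a[1])
  # arc from P4 to P1 around the distal pole (not through the shaft mouth):
  # pick the sweep direction that does not cross the shaft direction aA
  delta <- (a1 - a4) %% (2 * pi)
  if (((aA - a4) %% (2 * pi)) < delta) delta <- delta - 2 * pi
  aa <- seq(a4, a4 + delta, length.out = 60)
  arc <- cbind(C[1] + r * cos(aa), C[2] + r * sin(aa))
  femur_ring <- rbind(P1, P2, P3, P4, arc[-c(1, nrow(arc)), , drop = FALSE])
  dfr <- function(phi) cos(phi * pi / 180) * (-a) + sin(phi * pi / 180) * n
  K3 <- C + r * dfr(50)                 # distal-posterior femoral surface
  K7 <- C + r * dfr(-40)                # distal-anterior femoral surface
  K1 <- C + 0.55 * r * n + 0.10 * r * a # Blumensaat deep (posterior) end
  K2 <- C - 0.50 * r * n - 0.35 * r * a # Blumensaat shallow (anterior) end
  L1 <- rbind(K1, K2)
  t_lo <- s + 0.1 * par$L_f
  L2 <- rbind(C + (par$w_f / 2) * n + t_lo * a,
              C + (par$w_f / 2) * n + L * a)  # posterior cortex segment
  # --- tibia ---
  b <- unitv(90 + par$tibia_tilt)       # shaft direction, distal (down)
  m <- c(-b[2], b[1]); if (m[1] < 0) m <- -m  # posterior AP direction
  Pt <- C + (r - par$overlap) * c(-a[1], -a[2]) + 2 * m  # plateau top center
  K4 <- Pt - par$R_ap * m               # anterior plateau endpoint
  K5 <- Pt + par$R_ap * m               # posterior plateau endpoint
  xs <- seq(-par$R_ap, par$R_ap, length.out = 31)
  sag <- 2.5 * (1 - (xs / par$R_ap)^2)
  top <- t(vapply(seq_along(xs), function(i) Pt + xs[i] * m + sag[i] * b,
                  numeric(2)))
  top[1, ] <- K4; top[nrow(top), ] <- K5
  c_off <- runif(1, -4, 4)
  taper <- 8
  K6 <- K5 + 0.6 * par$h_p * b          # posterior facet (champagne drop-off)
  post_corner <- K5 + par$h_p * b
  ant_corner <- K4 + par$h_p * b
  Qp <- Pt + (c_off + par$w_t / 2) * m + (par$h_p + taper) * b
  Qp2 <- Pt + (c_off + par$w_t / 2) * m + par$L_t * b
  Qa2 <- Pt + (c_off - par$w_t / 2) * m + par$L_t * b
  Qa <- Pt + (c_off - par$w_t / 2) * m + (par$h_p + taper) * b
  tibia_ring <- rbind(top, K6, post_corner, Qp, Qp2, Qa2, Qa, ant_corner)
  L3 <- rbind(Pt + c_off * m + par$h_p * b, Pt + c_off * m + par$L_t * b)
  # --- pose everything into the image frame ---
  px <- function(xy) apply_similarity(matrix(xy, ncol = 2), pose)
  kp_list <- list(
    K1 = px(K1), K2 = px(K2), K3 = px(K3), K4 = px(K4), K5 = px(K5),
    K6 = px(K6), K7 = px(K7))
  keypoints <- lapply(names(kp_list), function(nm) {
    p <- kp_list[[nm]]; keypoint(p[1], p[2], nm, confidence = 1)
  })
  names(keypoints) <- names(kp_list)
  # shaft-attached lines are truncated by the field of view: clip the posed
  # segments to the frame (the bone polygons themselves may exceed it)
  mrg <- max(2.5, 4 * min(H, W) / 256)
  L2p <- clip_segment(px(L2), c(mrg, W - 1 - mrg), c(mrg, H - 1 - mrg))
  L3p <- clip_segment(px(L3), c(mrg, W - 1 - mrg), c(mrg, H - 1 - mrg))
  if (is.null(L2p) || is.null(L3p) ||
      seg_len(L2p) < 0.12 * min(H, W) || seg_len(L3p) < 0.12 * min(H, W)) {
    return(NULL)
  }
  lines <- list(L1 = polyline(px(L1), "L1"), L2 = polyline(L2p, "L2"),
                L3 = polyline(L3p, "L3"))
  regions <- list(
    S1 = apply_similarity(polygon_region(femur_ring, label = "S1"), pose),
    S2 = apply_similarity(polygon_region(tibia_ring, label = "S2"), pose))
  # chirality cues rendered in the image but not annotated: the fibula
  # (posterior to the tibial shaft) and the patella (anterior to the
  # femoral condyle), as on a real lateral projection
  fib_top <- Pt + (0.85 * par$R_ap + 6) * m + (par$h_p + 10) * b
  fib_bot <- Pt + (0.85 * par$R_ap + 2) * m + (0.85 * par$L_t) * b
  fibula <- px(rbind(fib_top, fib_bot))
  pat_c <- C - (r + 10) * n - 0.15 * r * a
  pth <- seq(0, 2 * pi, length.out = 25)[-25]
  pat_u <- -n; pat_v <- a
  patella <- t(vapply(pth, function(t_) {
    pat_c + 7 * cos(t_) * pat_u + 16 * sin(t_) * pat_v
  }, numeric(2)))
  pose_scale <- sqrt(abs(det(pose$A)))
  list(keypoints = keypoints, lines = lines, regions = regions, pose = pose,
       fibula = fibula, fibula_halfwidth = 6 * pose_scale,
       patella = apply_similarity(patella, pose))
}

phantom_in_frame <- function(geo, H, W, margin = 2) {
  if (is.null(geo)) return(FALSE)
  pts <- do.call(rbind, c(
    lapply(geo$keypoints, function(k) c(k$x, k$y)),
    lapply(geo$lines, function(l) l$points)))
  all(pts[, 1] >= margin, pts[, 1] < W - margin,
      pts[, 2] >= margin, pts[, 2] < H - margin)
}

seg_len <- function(seg) sqrt(sum((seg[2, ] - seg[1, ])^2))

# Liang-Barsky clipping of a segment to an axis-aligned box.
clip_segment <- function(seg, xlim, ylim) {
  p <- seg[1, ]; d <- seg[2, ] - seg[1, ]
  t0 <- 0; t1 <- 1
  for (k in 1:2) {
    lim <- if (k == 1) xlim else ylim
    if (abs(d[k]) < 1e-12) {
      if (p[k] < lim[1] || p[k] > lim[2]) return(NULL)
    } else {
      ta <- (lim[1] - p[k]) / d[k]; tb <- (lim[2] - p[k]) / d[k]
      if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
      t0 <- max(t0, ta); t1 <- min(t1, tb)
      if (t0 > t1) return(NULL)
    }
  }
  rbind(p + t0 * d, p + t1 * d)
}

render_phantom <- function(geo, par, cfg, H, W) {
  u <- min(H, W) / 256
  mask <- rasterize_mask(geo$regions, c(H, W))
  img <- 0.55 * mask$channels$S1 + 0.45 * mask$channels$S2
  # visible intercondylar ridge so the Blumensaat endpoints are learnable
  ridge <- cpp_line_heatmap(geo$lines$L1$points, H, W, max(1.2 * u, 0.8))
  img <- img + 0.3 * ridge
  # unannotated chiral anatomy: fibula (posterior) and patella (anterior)
  fib <- cpp_line_heatmap(geo$fibula, H, W,
                          max(geo$fibula_halfwidth, 1)) > exp(-0.5)
  img <- img + 0.3 * fib
  pat <- tryCatch(
    rasterize_polygon(polygon_region(geo$patella, label = "pat"), H, W),
    error = function(e) matrix(0, H, W))
  img <- img + 0.3 * pat
  if (par$implant) {
    nimp <- 1 + (runif(1) < 0.4)
    for (i in seq_len(nimp)) {
      icx <- runif(1, 0.3, 0.7) * W; icy <- runif(1, 0.3, 0.8) * H
      iw <- runif(1, 6, 14) * u; il <- runif(1, 30, 80) * u
      iang <- runif(1, 0, 180)
      d <- unitv(iang)
      seg <- rbind(c(icx, icy) - il / 2 * d, c(icx, icy) + il / 2 * d)
      img <- img + 2.2 * (cpp_line_heatmap(seg, H, W, iw / 2) > exp(-0.5))
    }
  }
  if (par$bilateral) {
    # faint contralateral ghost: shifted, mirrored copy of the bone fields
    ghost <- 0.3 * (mask$channels$S1 + mask$channels$S2)
    shift <- round(runif(1, 0.35, 0.45) * W)
    g2 <- matrix(0, H, W)
    src <- ghost[, W:1]
    if (shift < W) g2[, (shift + 1):W] <- src[, 1:(W - shift)]
    img <- img + g2
  }
  img <- as.matrix(EBImage::gblur(img, sigma = max(1, 1.5 * u)))
  img <- img + rnorm(H * W, 0, par$noise_sd)
  normalize_intensity(img)
}

#' Generate an in-memory phantom dataset for training
#'
#' Convenience wrapper building `n` phantoms and the `samples`/`train`/
#' `val`/`test` structure consumed by [train()].
#'
#' @param cfg A [phantom_config()].
#' @param n Number of samples.
#' @param split Train/val/test fractions (sum to 1).
#' @return List: `samples` (image + features), `phantoms` (full
#'   `kp_phantom` objects), `train`, `val`, `test` index vectors.
#' @export
phantom_dataset <- function(cfg, n, split = c(0.7, 0.15, 0.15)) {
  stopifnot(abs(sum(split) - 1) < 1e-8, n >= 3)
  phantoms <- lapply(seq_len(n), function(i) generate_phantom(cfg, i))
  samples <- lapply(phantoms, function(ph) {
    list(image = ph$image, features = ph$features)
  })
  n_train <- round(split[1] * n); n_val <- round(split[2] * n)
  list(samples = samples, phantoms = phantoms,
       train = seq_len(n_train),
       val = seq(n_train + 1, n_train + n_val),
       test = if (n_train + n_val < n) seq(n_train + n_val + 1, n) else integer(0))
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` phantom samples (PNG image, labelme-compatible annotation
#' JSON, plan-truth JSON) plus a split manifest CSV. Regeneration with the
#' same config yields byte-identical annotations and manifest.
#'
#' @param cfg A [phantom_config()].
#' @param n Number of samples (>= 3).
#' @param split Train/val/test fractions summing to 1.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest tibble (columns `index`, `split`,
#'   `image`, `annotation`, `plan`).
#' @export
generate_dataset <- function(cfg, n, split = c(0.6, 0.2, 0.2), dir) {
  stopifnot(n >= 3, abs(sum(split) - 1) < 1e-8)
  n_train <- round(split[1] * n); n_val <- round(split[2] * n)
  n_test <- n - n_train - n_val
  if (min(n_train, n_val, n_test) < 1) stop("impossible split for n = ", n)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labels <- c(rep("train", n_train), rep("val", n_val), rep("test", n_test))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- generate_phantom(cfg, i)
    base <- sprintf("phantom_%04d", i)
    img_path <- file.path(dir, paste0(base, ".png"))
    ann_path <- file.path(dir, paste0(base, ".json"))
    plan_path <- file.path(dir, paste0(base, "_plan.json"))
    png::writePNG(ph$image, img_path)
    write_annotation(ph$features, dim(ph$image), ann_path,
                     image_path = paste0(base, ".png"))
    jsonlite::write_json(plan_to_list(ph$plan_truth), plan_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    rows[[i]] <- tibble::tibble(index = i, split = labels[i],
                                image = basename(img_path),
                                annotation = basename(ann_path),
                                plan = basename(plan_path),
                                mm_per_px = ph$calibration$mm_per_px)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

plan_to_list <- function(plans) {
  lapply(plans, function(p) {
    list(application = p$application, status = p$status, reason = p$reason,
         targets = lapply(p$targets, feature_to_list))
  })
}

feature_to_list <- function(f) {
  if (inherits(f, "kp_keypoint")) {
    list(type = "point", label = f$label, xy = c(f$x, f$y))
  } else if (inherits(f, "kp_polyline")) {
    list(type = "linestrip", label = f$label,
         points = apply(f$points, 1, function(r) as.list(r),
                        simplify = FALSE))
  } else NULL
}

#' @export
print.kp_phantom <- function(x, ...) {
  cat(sprintf("<phantom #%d> %dx%d %s, mm/px=%.3f%s%s%s\n", x$index,
              nrow(x$image), ncol(x$image), x$params$preset %||% "",
              x$calibration$mm_per_px,
              if (x$params$truncated) ", truncated" else "",
              if (x$params$implant) ", implant" else "",
              if (x$params$bilateral) ", bilateral" else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
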