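# Stage C: parameterized geometric constructions that turn named anatomical
# features into surgical plans (MPFL Schoettle point, ACL femoral quadrant
# and tibial AP-fraction targets, PCL transtibial guidewire), with
# deterministic re-execution after user edits.
#
# Blueprint constants (quadrant fractions, AP fractions, mm offsets, wire
# angle) are configuration values with documented defaults taken from the
# cited clinical planning literature; they are NON-NORMATIVE defaults and
# are expected to be reviewed per deployment.

#' Decoded feature set
#'
#' Container shared by ground truth, network predictions and user edits:
#' keypoints, polylines and polygon regions keyed by their registry label,
#' plus a provenance map (`automatic` / `user_edited` / `ground_truth`).
#'
#' @param keypoints,lines,regions Named lists of [keypoint()],
#'   [polyline()], [polygon_region()] (or [not_detected()]).
#' @param provenance Named character vector feature label -> provenance.
#' @return A `kp_features` object.
#' @export
feature_set <- function(keypoints = list(), lines = list(),
                        regions = list(), provenance = character()) {
  name_by_label <- function(lst) {
    if (length(lst) == 0) return(lst)
    labs <- vapply(lst, function(f) {
      if (is_detected(f)) f$label else NA_character_
    }, character(1))
    if (is.null(names(lst))) names(lst) <- labs
    lst
  }
  structure(list(keypoints = name_by_label(keypoints),
                 lines = name_by_label(lines),
                 regions = name_by_label(regions),
                 provenance = provenance),
            class = "kp_features")
}

#' @export
print.kp_features <- function(x, ...) {
  cat(sprintf("<feature set> %d keypoints, %d lines, %d regions\n",
              length(x$keypoints), length(x$lines), length(x$regions)))
  invisible(x)
}

get_feature <- function(features, slot, label) {
  f <- features[[slot]][[label]]
  if (is.null(f)) return(not_detected(sprintf("%s '%s' missing", slot, label)))
  f
}

#' Default feature registry
#'
#' The mapping from blueprint roles to feature labels. The label semantics
#' are those of the phantom generator: `K1`/`K2` endpoints of the
#' Blumensaat line (`L1`), `K3`/`K7` distal femoral surface points for the
#' MPFL construction, `K4`/`K5` anterior/posterior tibial plateau
#' endpoints, `K6` the posterior tibial facet landmark, `L2` the posterior
#' femoral cortex, `L3` the tibial shaft axis, `S1` femur, `S2` tibia.
#' Deployments with different annotation schemes rebind the roles here.
#'
#' @return Named list of role -> label bindings per application.
#' @export
feature_registry <- function() {
  list(
    MPFL = list(kp_a = "K3", kp_b = "K7", cortex = "L2", femur = "S1"),
    ACL_femur = list(kp_deep = "K1", kp_shallow = "K2", condyle = "S1"),
    ACL_tibia = list(kp_anterior = "K4", kp_posterior = "K5"),
    PCL = list(kp_facet = "K6", shaft_axis = "L3")
  )
}

#' Planning blueprint
#'
#' @param application One of `"MPFL"`, `"ACL_femur"`, `"ACL_tibia"`,
#'   `"PCL"`.
#' @param constants Named list of construction constants; missing entries
#'   take the documented defaults of [default_blueprint()].
#' @param roles Role -> feature-label bindings; defaults from
#'   [feature_registry()].
#' @return A `kp_blueprint`.
#' @export
blueprint <- function(application = c("MPFL", "ACL_femur", "ACL_tibia", "PCL"),
                      constants = list(), roles = NULL) {
  application <- match.arg(application)
  def <- default_blueprint(application)
  def$constants[names(constants)] <- constants
  cst <- def$constants
  fr <- c("t_u_am", "t_v_am", "t_u_pl", "t_v_pl", "t_am", "t_pl")
  for (f in intersect(fr, names(cst))) {
    if (cst[[f]] < 0 || cst[[f]] > 1) {
      stop(sprintf("blueprint fraction %s must lie in [0, 1]", f))
    }
  }
  if (!is.null(roles)) def$roles[names(roles)] <- roles
  structure(list(application = application, constants = cst,
                 roles = def$roles),
            class = "kp_blueprint")
}

#' Default blueprint constants per application
#'
#' MPFL: Schoettle-type construction (perpendicular feet of two distal
#' femoral keypoints on the posterior cortex extension line; 2.5 mm
#' clinical tolerance radius). ACL femur: quadrant-method fractions of the
#' Blumensaat-aligned condyle rectangle. ACL tibia: AP-diameter fractions.
#' PCL: transtibial guidewire from the posterior facet landmark with an
#' mm offset along the shaft axis and a fixed wire angle to it.
#'
#' @param application Application id.
#' @return List with `constants` and `roles`.
#' @export
default_blueprint <- function(application) {
  reg <- feature_registry()
  switch(application,
    MPFL = list(constants = list(anterior_offset_mm = 0,
                                 tolerance_mm = 2.5),
                roles = reg$MPFL),
    ACL_femur = list(constants = list(t_u_am = 0.217, t_v_am = 0.332,
                                      t_u_pl = 0.351, t_v_pl = 0.553),
                     roles = reg$ACL_femur),
    ACL_tibia = list(constants = list(t_am = 0.366, t_pl = 0.465),
                     roles = reg$ACL_tibia),
    PCL = list(constants = list(offset_mm = 10, wire_angle_deg = 55,
                                wire_length_mm = 60),
               roles = reg$PCL),
    stop("unknown application: ", application))
}

plan_result <- function(application, status = "ok", reason = NULL,
                        targets = list(), intermediates = list(),
                        units = "px") {
  structure(list(application = application, status = status, reason = reason,
                 targets = targets, intermediates = intermediates,
                 units = units),
            class = "kp_plan")
}

cancelled_plan <- function(application, reason) {
  plan_result(application, status = "cancelled", reason = reason)
}

#' @export
print.kp_plan <- function(x, ...) {
  if (x$status != "ok") {
    cat(sprintf("<%s plan> CANCELLED: %s\n", x$application, x$reason))
  } else {
    cat(sprintf("<%s plan> ok; targets: %s\n", x$application,
                paste(names(x$targets), collapse = ", ")))
  }
  invisible(x)
}

# Total-least-squares (orthogonal regression) line through points:
# returns centroid and unit direction (first principal axis).
tls_line <- function(pts) {
  ctr <- colMeans(pts)
  cc <- sweep(pts, 2, ctr)
  d <- eigen(crossprod(cc) / nrow(pts), symmetric = TRUE)$vectors[, 1]
  list(point = ctr, dir = d / sqrt(sum(d^2)))
}

project_on_line <- function(p, line) {
  as.numeric(line$point + sum((p - line$point) * line$dir) * line$dir)
}

line_as_polyline <- function(line, half_len, label) {
  polyline(rbind(line$point - half_len * line$dir,
                 line$point + half_len * line$dir), label = label)
}

#' MPFL femoral insertion (Schoettle-type construction)
#'
#' Fits the posterior cortex extension line by total least squares through
#' the cortex contour subsection, drops perpendiculars from the two distal
#' femoral keypoints onto it, and places the target at the midpoint of the
#' two perpendicular feet, optionally offset anteriorly (toward the side
#' of the keypoints) by `anterior_offset_mm`. A 2.5 mm tolerance circle is
#' attached when a calibration is available.
#'
#' @param features A [feature_set()].
#' @param bp A [blueprint()] for `"MPFL"` (default blueprint if omitted).
#' @param cal Optional [calibration()].
#' @return A `kp_plan`.
#' @export
plan_mpfl <- function(features, bp = blueprint("MPFL"), cal = NULL) {
  ka <- get_feature(features, "keypoints", bp$roles$kp_a)
  kb <- get_feature(features, "keypoints", bp$roles$kp_b)
  cortex <- get_feature(features, "lines", bp$roles$cortex)
  for (f in list(ka, kb, cortex)) {
    if (!is_detected(f)) return(cancelled_plan("MPFL", f$reason))
  }
  pa <- c(ka$x, ka$y); pb <- c(kb$x, kb$y)
  if (sqrt(sum((pa - pb)^2)) < 1e-9) {
    return(cancelled_plan("MPFL", "degenerate: keypoints coincident"))
  }
  cl <- tls_line(cortex$points)
  fa <- project_on_line(pa, cl)
  fb <- project_on_line(pb, cl)
  target <- (fa + fb) / 2
  off_mm <- bp$constants$anterior_offset_mm
  if (off_mm != 0) {
    if (is.null(cal) || cal$source == "none") {
      return(cancelled_plan("MPFL", "anterior offset requires calibration"))
    }
    nrm <- c(-cl$dir[2], cl$dir[1])
    centroid <- (pa + pb) / 2
    if (sum((centroid - target) * nrm) < 0) nrm <- -nrm  # anterior = keypoint side
    target <- target + (off_mm / cal$mm_per_px) * nrm
  }
  tol_px <- if (!is.null(cal) && cal$source != "none") {
    bp$constants$tolerance_mm / cal$mm_per_px
  } else NA_real_
  half <- max(sqrt(sum((fa - fb)^2)), 20)
  plan_result(
    "MPFL",
    targets = list(insertion = keypoint(target[1], target[2], "mpfl_insertion")),
    intermediates = list(
      cortex_line = line_as_polyline(cl, 2 * half, "cortex_extension"),
      foot_a = keypoint(fa[1], fa[2], "foot_a"),
      foot_b = keypoint(fb[1], fb[2], "foot_b"),
      tolerance_radius_px = tol_px),
    units = if (is.na(tol_px)) "px" else "px+mm")
}

#' ACL femoral tunnel targets (quadrant method)
#'
#' Builds the quadrant frame on the Blumensaat segment (deep keypoint ->
#' shallow keypoint as u axis, perpendicular v axis oriented toward the
#' condyle), sizes the rectangle to the condyle contour extents along u
#' and v, and places the anteromedial (AM) and posterolateral (PL) bundle
#' targets at the blueprint's fractional coordinates of the rectangle.
#'
#' @inheritParams plan_mpfl
#' @param bp A [blueprint()] for `"ACL_femur"`.
#' @return A `kp_plan` with targets `am` and `pl`.
#' @export
plan_acl_femur <- function(features, bp = blueprint("ACL_femur"), cal = NULL) {
  k1 <- get_feature(features, "keypoints", bp$roles$kp_deep)
  k2 <- get_feature(features, "keypoints", bp$roles$kp_shallow)
  condyle <- get_feature(features, "regions", bp$roles$condyle)
  for (f in list(k1, k2, condyle)) {
    if (!is_detected(f)) return(cancelled_plan("ACL_femur", f$reason))
  }
  p1 <- c(k1$x, k1$y); p2 <- c(k2$x, k2$y)
  if (sqrt(sum((p2 - p1)^2)) < 1e-9) {
    return(cancelled_plan("ACL_femur", "degenerate: Blumensaat keypoints coincident"))
  }
  u <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
  v <- c(-u[2], u[1])
  pts <- condyle$outer
  ctr <- colMeans(pts)
  if (sum((ctr - p1) * v) < 0) v <- -v  # v points into the condyle
  pu <- as.numeric(sweep(pts, 2, p1) %*% u)
  pv <- as.numeric(sweep(pts, 2, p1) %*% v)
  frame_pt <- function(tu, tv) {
    q <- p1 + (min(pu) + tu * diff(range(pu))) * u +
      (min(pv) + tv * diff(range(pv))) * v
    q
  }
  am <- frame_pt(bp$constants$t_u_am, bp$constants$t_v_am)
  pl <- frame_pt(bp$constants$t_u_pl, bp$constants$t_v_pl)
  corners <- rbind(frame_pt(0, 0), frame_pt(1, 0), frame_pt(1, 1),
                   frame_pt(0, 1))
  plan_result(
    "ACL_femur",
    targets = list(am = keypoint(am[1], am[2], "acl_femur_am"),
                   pl = keypoint(pl[1], pl[2], "acl_femur_pl")),
    intermediates = list(
      blumensaat = polyline(rbind(p1, p2), "blumensaat"),
      quadrant_frame = polyline(corners, "quadrant_frame", closed = TRUE)))
}

#' ACL tibial tunnel targets (AP-diameter fractions)
#'
#' Places the AM and PL bundle targets on the anterior-posterior plateau
#' diameter segment at the blueprint's fractions of its length, measured
#' from the anterior endpoint.
#'
#' @inheritParams plan_mpfl
#' @param bp A [blueprint()] for `"ACL_tibia"`.
#' @return A `kp_plan` with targets `am` and `pl`.
#' @export
plan_acl_tibia <- function(features, bp = blueprint("ACL_tibia"), cal = NULL) {
  ka <- get_feature(features, "keypoints", bp$roles$kp_anterior)
  kp_ <- get_feature(features, "keypoints", bp$roles$kp_posterior)
  for (f in list(ka, kp_)) {
    if (!is_detected(f)) return(cancelled_plan("ACL_tibia", f$reason))
  }
  a <- c(ka$x, ka$y); b <- c(kp_$x, kp_$y)
  if (sqrt(sum((b - a)^2)) < 1e-9) {
    return(cancelled_plan("ACL_tibia", "degenerate: AP endpoints coincident"))
  }
  am <- a + bp$constants$t_am * (b - a)
  pl <- a + bp$constants$t_pl * (b - a)
  plan_result(
    "ACL_tibia",
    targets = list(am = keypoint(am[1], am[2], "acl_tibia_am"),
                   pl = keypoint(pl[1], pl[2], "acl_tibia_pl")),
    intermediates = list(ap_diameter = polyline(rbind(a, b), "ap_diameter")))
}

#' PCL transtibial guidewire plan
#'
#' Displaces the posterior tibial facet landmark by `offset_mm` along the
#' tibial shaft axis (distally, i.e. the +y oriented direction of the
#' fitted axis) and constructs the guidewire through the insertion point
#' at `wire_angle_deg` to the shaft axis. PCL planning refuses to run
#' without a pixel-to-mm calibration because its constants are metric.
#'
#' @inheritParams plan_mpfl
#' @param bp A [blueprint()] for `"PCL"`.
#' @param cal A [calibration()]; `source = "none"` cancels the plan.
#' @return A `kp_plan` with targets `insertion` and `guidewire`, plus the
#'   k-wire angulation in degrees.
#' @export
plan_pcl <- function(features, bp = blueprint("PCL"), cal = NULL) {
  if (is.null(cal) || cal$source == "none" || !is.finite(cal$mm_per_px)) {
    return(cancelled_plan("PCL", "no-scale: pixel-to-mm calibration required"))
  }
  kf <- get_feature(features, "keypoints", bp$roles$kp_facet)
  axis <- get_feature(features, "lines", bp$roles$shaft_axis)
  for (f in list(kf, axis)) {
    if (!is_detected(f)) return(cancelled_plan("PCL", f$reason))
  }
  al <- tls_line(axis$points)
  d <- al$dir
  if (d[2] < 0) d <- -d  # orient distally (y grows downward)
  p0 <- c(kf$x, kf$y)
  insertion <- p0 + (bp$constants$offset_mm / cal$mm_per_px) * d
  th <- bp$constants$wire_angle_deg * pi / 180
  wd <- c(cos(th) * d[1] - sin(th) * d[2], sin(th) * d[1] + cos(th) * d[2])
  half <- (bp$constants$wire_length_mm / 2) / cal$mm_per_px
  wire <- polyline(rbind(insertion - half * wd, insertion + half * wd),
                   "guidewire")
  wire_angle <- atan2(wd[2], wd[1]) * 180 / pi
  plan_result(
    "PCL",
    targets = list(
      insertion = keypoint(insertion[1], insertion[2], "pcl_insertion"),
      guidewire = wire),
    intermediates = list(
      shaft_axis = line_as_polyline(al, 4 * bp$constants$offset_mm / cal$mm_per_px,
                                    "shaft_axis"),
      wire_angle_deg = wire_angle,
      wire_angle_to_axis_deg = bp$constants$wire_angle_deg),
    units = "px+mm")
}

#' Execute (or re-execute) a plan with user edits
#'
#' Pure function: the features are overridden by the user-supplied edits
#' (keyed by blueprint role), then the application's planning operation is
#' re-run from scratch. Identical inputs yield identical outputs, so the
#' plan can be recomputed in real time after each edit.
#'
#' @param features A [feature_set()].
#' @param bp A [blueprint()].
#' @param edits Named list role -> replacement feature ([keypoint()],
#'   [polyline()] or [polygon_region()]).
#' @param cal Optional [calibration()].
#' @return A `kp_plan`.
#' @export
execute_plan <- function(features, bp, edits = list(), cal = NULL) {
  if (length(edits)) {
    unknown <- setdiff(names(edits), names(bp$roles))
    if (length(unknown)) {
      stop("unknown blueprint role(s) in edits: ",
           paste(unknown, collapse = ", "))
    }
    for (role in names(edits)) {
      lab <- bp$roles[[role]]
      f <- edits[[role]]
      slot <- if (inherits(f, "kp_keypoint")) "keypoints"
              else if (inherits(f, "kp_polyline")) "lines"
              else if (inherits(f, "kp_polygon")) "regions"
              else stop("edit for role '", role, "' is not a feature")
      f$label <- lab
      features[[slot]][[lab]] <- f
      features$provenance[lab] <- "user_edited"
    }
  }
  fn <- switch(bp$application, MPFL = plan_mpfl, ACL_femur = plan_acl_femur,
               ACL_tibia = plan_acl_tibia, PCL = plan_pcl)
  fn(features, bp, cal)
}
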