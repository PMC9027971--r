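#' @useDynLib kneeplanr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef median optimize prcomp quantile runif rnorm sd
NULL

# Coordinate convention used throughout the package: 0-based continuous
# coordinates, x rightwards, y downwards, origin at the center of the
# top-left pixel; image domain is the half-open box [0, W) x [0, H).
# Angles are in degrees from the +x axis; positive rotation is
# counter-clockwise in the displayed (y-down) image. Undirected line
# orientations are reported in (-90, 90].

#' Anatomical keypoint
#'
#' A single sub-pixel landmark coordinate, optionally carrying the decoded
#' heatmap peak height as a confidence in `[0, 1]`.
#'
#' @param x,y Continuous pixel coordinates (0-based, pixel-center origin).
#' @param label Feature id, e.g. `"K1"`.
#' @param confidence Optional decoded peak height in `[0, 1]`.
#' @return A `kp_keypoint` object.
#' @export
keypoint <- function(x, y, label = NA_character_, confidence = NA_real_) {
  stopifnot(is.finite(x), is.finite(y))
  if (!is.na(confidence) && (confidence < 0 || confidence > 1)) {
    stop("confidence must lie in [0, 1]")
  }
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 label = as.character(label),
                 confidence = as.numeric(confidence)),
            class = "kp_keypoint")
}

#' Polyline feature
#'
#' An ordered open (or closed) chain of continuous coordinates, used for
#' anatomical lines and axes.
#'
#' @param points Numeric n x 2 matrix of (x, y) coordinates, n >= 2.
#' @param label Feature id, e.g. `"L1"`.
#' @param closed Logical; `TRUE` for closed rings.
#' @return A `kp_polyline` object.
#' @export
polyline <- function(points, label = NA_character_, closed = FALSE) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, nrow(points) >= 2, all(is.finite(points)))
  dup <- rowSums(abs(diff(points))) == 0
  if (any(dup)) points <- points[c(TRUE, !dup), , drop = FALSE]
  if (nrow(points) < 2) stop("polyline needs >= 2 distinct points")
  dimnames(points) <- NULL
  structure(list(points = points, label = as.character(label),
                 closed = isTRUE(closed)),
            class = "kp_polyline")
}

#' Polygonal region
#'
#' A simple outer ring with optional holes; used for bone outlines
#' (femur `S1`, tibia `S2`).
#'
#' @param outer Numeric n x 2 matrix of ring coordinates (not repeated at
#'   the end), n >= 3.
#' @param holes Optional list of hole rings (n x 2 matrices).
#' @param label Structure id, e.g. `"S1"`.
#' @return A `kp_polygon` object.
#' @export
polygon_region <- function(outer, holes = list(), label = NA_character_) {
  outer <- as.matrix(outer)
  stopifnot(ncol(outer) == 2, nrow(outer) >= 3, all(is.finite(outer)))
  if (all(outer[1, ] == outer[nrow(outer), ])) {
    outer <- outer[-nrow(outer), , drop = FALSE]
  }
  if (abs(shoelace_area(outer)) <= 0) stop("degenerate polygon (area 0)")
  holes <- lapply(holes, function(h) {
    h <- as.matrix(h)
    if (all(h[1, ] == h[nrow(h), ])) h <- h[-nrow(h), , drop = FALSE]
    h
  })
  dimnames(outer) <- NULL
  structure(list(outer = outer, holes = holes, label = as.character(label)),
            class = "kp_polygon")
}

#' Signed shoelace area of a ring
#'
#' Positive for counter-clockwise rings in the y-down frame convention of
#' this package (i.e. clockwise on screen).
#'
#' @param ring n x 2 coordinate matrix.
#' @return Signed area in px^2.
#' @export
shoelace_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

#' Pixel-to-mm calibration
#'
#' @param mm_per_px Scale factor in mm per pixel (> 0 unless uncalibrated).
#' @param source One of `"sphere"`, `"manual"`, `"none"`.
#' @return A `kp_calibration` object.
#' @export
calibration <- function(mm_per_px = NA_real_, source = c("manual", "sphere", "none")) {
  source <- match.arg(source)
  if (source != "none" && (!is.finite(mm_per_px) || mm_per_px <= 0)) {
    stop("invalid calibration: mm_per_px must be > 0")
  }
  structure(list(mm_per_px = as.numeric(mm_per_px), source = source),
            class = "kp_calibration")
}

#' Calibrate from a reference sphere
#'
#' Radiographs carrying a steel calibration sphere of known physical
#' diameter (30 mm by convention) yield the pixel-to-mm scale as the ratio
#' of physical to projected diameter.
#'
#' @param sphere_diameter_px Measured sphere diameter in pixels.
#' @param sphere_diameter_mm Physical sphere diameter in mm (default 30).
#' @return A `kp_calibration` with `source = "sphere"`.
#' @examples
#' calibrate_from_sphere(100)  # 0.3 mm/px
#' @export
calibrate_from_sphere <- function(sphere_diameter_px, sphere_diameter_mm = 30) {
  if (!is.finite(sphere_diameter_px) || sphere_diameter_px <= 0 ||
      !is.finite(sphere_diameter_mm) || sphere_diameter_mm <= 0) {
    stop("invalid calibration: sphere diameters must be > 0")
  }
  calibration(sphere_diameter_mm / sphere_diameter_px, "sphere")
}

#' 2D similarity transform
#'
#' Rotation (degrees, standard mathematical sense applied to the raw (x, y)
#' coordinates: +90 degrees maps (10, 0) to (0, 10)), isotropic scale,
#' translation, and optional mirroring about the y axis (applied first).
#' The transform maps `p -> s * R * M * p + t`.
#'
#' @param angle_deg Rotation angle in degrees.
#' @param scale Isotropic scale (> 0).
#' @param tx,ty Translation in px.
#' @param mirror Mirror x -> -x before rotating.
#' @return A `kp_transform` holding the 2x2 linear part and offset.
#' @export
similarity_transform <- function(angle_deg = 0, scale = 1, tx = 0, ty = 0,
                                 mirror = FALSE) {
  if (!is.finite(scale) || scale <= 0) stop("scale must be > 0")
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  M <- diag(c(if (mirror) -1 else 1, 1))
  structure(list(A = scale * R %*% M, t = c(tx, ty),
                 mirror = isTRUE(mirror)),
            class = "kp_transform")
}

#' Compose two similarity transforms
#'
#' `compose_transform(g, f)` applies `f` first, then `g`.
#'
#' @param g,f `kp_transform` objects.
#' @return The composed `kp_transform`.
#' @export
compose_transform <- function(g, f) {
  structure(list(A = g$A %*% f$A, t = as.numeric(g$A %*% f$t + g$t),
                 mirror = xor(g$mirror, f$mirror)),
            class = "kp_transform")
}

#' Invert a similarity transform
#'
#' @param tf A `kp_transform`.
#' @return The inverse `kp_transform`.
#' @export
invert_transform <- function(tf) {
  Ai <- solve(tf$A)
  structure(list(A = Ai, t = as.numeric(-Ai %*% tf$t), mirror = tf$mirror),
            class = "kp_transform")
}

transform_xy <- function(xy, tf) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  sweep(xy %*% t(tf$A), 2, tf$t, `+`)
}

#' Apply a similarity transform to a geometric feature
#'
#' Maps every coordinate of the feature; type, label and vertex ordering
#' are preserved. After mirroring, polygon ring orientation is
#' re-normalized so the outer ring keeps positive area.
#'
#' @param feature A `kp_keypoint`, `kp_polyline` or `kp_polygon`.
#' @param tf A `kp_transform`.
#' @return Feature of the same type.
#' @export
apply_similarity <- function(feature, tf) UseMethod("apply_similarity")

#' @export
apply_similarity.kp_keypoint <- function(feature, tf) {
  p <- transform_xy(c(feature$x, feature$y), tf)
  keypoint(p[1], p[2], feature$label, feature$confidence)
}

#' @export
apply_similarity.kp_polyline <- function(feature, tf) {
  polyline(transform_xy(feature$points, tf), feature$label, feature$closed)
}

#' @export
apply_similarity.kp_polygon <- function(feature, tf) {
  outer <- transform_xy(feature$outer, tf)
  if (shoelace_area(outer) < 0) outer <- outer[nrow(outer):1, , drop = FALSE]
  holes <- lapply(feature$holes, function(h) {
    h <- transform_xy(h, tf)
    if (shoelace_area(h) > 0) h <- h[nrow(h):1, , drop = FALSE]
    h
  })
  polygon_region(outer, holes, feature$label)
}

#' @export
apply_similarity.matrix <- function(feature, tf) transform_xy(feature, tf)

#' Convert pixel lengths to mm
#'
#' @param px Length(s) in pixels.
#' @param cal A `kp_calibration`, or `NULL` for uncalibrated.
#' @return Length in mm, or `NA` when uncalibrated.
#' @export
px_to_mm <- function(px, cal) {
  if (is.null(cal) || cal$source == "none") return(rep(NA_real_, length(px)))
  px * cal$mm_per_px
}

#' @export
print.kp_keypoint <- function(x, ...) {
  cat(sprintf("<keypoint %s> (%.3f, %.3f)", x$label, x$x, x$y))
  if (!is.na(x$confidence)) cat(sprintf(" conf=%.3f", x$confidence))
  cat("\n")
  invisible(x)
}

#' @export
print.kp_polyline <- function(x, ...) {
  cat(sprintf("<polyline %s> %d points%s\n", x$label, nrow(x$points),
              if (x$closed) " (closed)" else ""))
  invisible(x)
}

#' @export
print.kp_polygon <- function(x, ...) {
  cat(sprintf("<polygon %s> %d vertices, area %.1f px^2\n", x$label,
              nrow(x$outer), abs(shoelace_area(x$outer))))
  invisible(x)
}
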