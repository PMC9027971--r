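# Spatial representations learned by the network: Gaussian keypoint
# heatmaps, line-symmetric heatmaps, and multi-label (overlap-aware)
# binary masks. Encoded heatmaps use an unnormalized Gaussian (peak value 1
# at the feature) truncated at +-3 sigma: values at distance <= 3 sigma are
# kept, everything beyond is exactly zero.

new_heatmap <- function(grid, sigma, kind) {
  structure(grid, sigma = sigma, kind = kind,
            class = c("kp_heatmap", "matrix", "array"))
}

#' Heatmap constructor
#'
#' Wraps a numeric `H x W` grid of likelihoods as a heatmap object. Rows
#' index y, columns index x (pixel `(x, y)` lives at `grid[y + 1, x + 1]`).
#'
#' @param grid Numeric matrix with values expected in `[0, 1]` for encoded
#'   ground truth (raw network regressions may exceed the range and are
#'   clamped at decoding).
#' @param sigma Encoding standard deviation in px.
#' @param kind `"keypoint"` or `"line"`.
#' @return A `kp_heatmap`.
#' @export
heatmap_grid <- function(grid, sigma = 6, kind = c("keypoint", "line")) {
  kind <- match.arg(kind)
  new_heatmap(as.matrix(grid), sigma, kind)
}

#' Encode a keypoint as a truncated Gaussian heatmap
#'
#' The grid value at pixel center `p` is `exp(-|p - kp|^2 / (2 sigma^2))`
#' for `|p - kp| <= 3 sigma` and exactly 0 beyond, so the value at the
#' keypoint coordinate itself is 1 (no normalization factor).
#'
#' @param kp A [keypoint()] inside the image domain.
#' @param shape Integer `(H, W)`.
#' @param sigma Standard deviation in px (default 6).
#' @return A `kp_heatmap` of kind `"keypoint"`.
#' @export
encode_keypoint <- function(kp, shape, sigma = 6) {
  H <- shape[1]; W <- shape[2]
  stopifnot(sigma > 0)
  if (kp$x < 0 || kp$x >= W || kp$y < 0 || kp$y >= H) {
    stop(sprintf("keypoint %s (%.1f, %.1f) outside image domain [0,%d)x[0,%d)",
                 kp$label, kp$x, kp$y, W, H))
  }
  xs <- (seq_len(W) - 1) - kp$x
  ys <- (seq_len(H) - 1) - kp$y
  d2 <- outer(ys^2, xs^2, `+`)
  g <- exp(-d2 / (2 * sigma^2))
  g[d2 > (3 * sigma)^2] <- 0
  new_heatmap(g, sigma, "keypoint")
}

#' Encode a polyline as a line-symmetric heatmap
#'
#' Pixels inside a locally-bounded hull around the polyline (orthogonal
#' distance at most `3 sigma`; the hull is capped past the endpoints by
#' round caps of the same radius, i.e. the distance-to-segment metric) take
#' the value `exp(-d^2 / (2 sigma^2))` where `d` is the distance to the
#' nearest point on the polyline; all other pixels are 0. The hull width
#' orthogonal to the line is `w = 6 sigma`.
#'
#' @param line A [polyline()].
#' @param shape Integer `(H, W)`.
#' @param sigma Standard deviation in px (default 6).
#' @return A `kp_heatmap` of kind `"line"`.
#' @export
encode_line <- function(line, shape, sigma = 6) {
  stopifnot(sigma > 0)
  pts <- line$points
  if (line$closed) pts <- rbind(pts, pts[1, ])
  if (sum(sqrt(rowSums(diff(pts)^2))) <= 0) stop("zero-length line")
  g <- cpp_line_heatmap(pts, as.integer(shape[1]), as.integer(shape[2]),
                        sigma)
  new_heatmap(g, sigma, "line")
}

#' Rasterize polygons into a multi-label mask
#'
#' One binary channel per region; a pixel is set iff its center lies inside
#' the polygon (even-odd rule; holes subtracted). Channels may overlap:
#' superimposed bones in transmissive imaging are represented per structure,
#' not as a partition.
#'
#' @param regions List of [polygon_region()].
#' @param shape Integer `(H, W)`.
#' @return A `kp_mask`: list with `channels` (named list of H x W 0/1
#'   matrices) and `shape`.
#' @export
rasterize_mask <- function(regions, shape) {
  H <- shape[1]; W <- shape[2]
  stopifnot(H >= 1, W >= 1)
  channels <- list()
  for (rg in regions) {
    if (abs(shoelace_area(rg$outer)) <= 0) stop("degenerate polygon")
    channels[[rg$label]] <- rasterize_polygon(rg, H, W)
  }
  structure(list(channels = channels, shape = c(H, W)), class = "kp_mask")
}

rasterize_polygon <- function(rg, H, W) {
  # stack outer ring and holes separated by NA rows; mgcv::in.out applies
  # the even-odd crossing rule across all loops
  bnd <- close_ring(rg$outer)
  for (h in rg$holes) bnd <- rbind(bnd, c(NA, NA), close_ring(h))
  xr <- range(bnd[, 1], na.rm = TRUE); yr <- range(bnd[, 2], na.rm = TRUE)
  xs <- max(0L, floor(xr[1])):min(W - 1L, ceiling(xr[2]))
  ys <- max(0L, floor(yr[1])):min(H - 1L, ceiling(yr[2]))
  m <- matrix(0, H, W)
  if (length(xs) == 0 || length(ys) == 0) return(m)
  pts <- cbind(rep(xs, each = length(ys)), rep(ys, times = length(xs)))
  inside <- mgcv::in.out(bnd, pts)
  m[cbind(pts[inside, 2] + 1L, pts[inside, 1] + 1L)] <- 1
  m
}

close_ring <- function(ring) rbind(ring, ring[1, , drop = FALSE])

#' Stack a multi-label mask into an array
#'
#' @param mask A `kp_mask`.
#' @return `H x W x C` numeric array (C = number of channels).
#' @export
mask_to_array <- function(mask) {
  C <- length(mask$channels)
  a <- array(0, c(mask$shape, max(C, 1L)))
  for (i in seq_len(C)) a[, , i] <- mask$channels[[i]]
  dimnames(a) <- list(NULL, NULL, names(mask$channels))
  a
}

#' @export
print.kp_heatmap <- function(x, ...) {
  cat(sprintf("<heatmap %s> %dx%d, sigma=%g, max=%.3f\n", attr(x, "kind"),
              nrow(x), ncol(x), attr(x, "sigma"), max(x)))
  invisible(x)
}

#' @export
print.kp_mask <- function(x, ...) {
  cat(sprintf("<multi-label mask> %dx%d, channels: %s\n", x$shape[1],
              x$shape[2], paste(names(x$channels), collapse = ", ")))
  invisible(x)
}
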