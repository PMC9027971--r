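# Stage B: transform inferred spatial encodings back into geometric
# objects. Decoders never crash on absent structures; they return a typed
# "not detected" result so downstream planning can cancel gracefully.

#' Not-detected sentinel
#'
#' @param reason Short machine-readable reason string.
#' @return A `kp_not_detected` object.
#' @export
not_detected <- function(reason = "no signal") {
  structure(list(reason = reason), class = "kp_not_detected")
}

#' Test whether a decoding result carries a feature
#'
#' @param x Any decoder output.
#' @return `FALSE` for [not_detected()] results, `TRUE` otherwise.
#' @export
is_detected <- function(x) !inherits(x, "kp_not_detected")

#' @export
print.kp_not_detected <- function(x, ...) {
  cat(sprintf("<not detected: %s>\n", x$reason))
  invisible(x)
}

#' Decode a keypoint by spatial argmax
#'
#' Returns the coordinate of the maximal grid cell, with ties broken
#' deterministically (lowest y, then lowest x). The clamped peak height is
#' reported as the confidence. Peaks below `floor` signal a failed
#' detection instead of returning a spurious coordinate.
#'
#' @param hm A `kp_heatmap` (or plain matrix).
#' @param floor Minimum acceptable peak value (default 0.05).
#' @param label Label to attach to the decoded keypoint.
#' @return A [keypoint()] or [not_detected()].
#' @export
decode_keypoint_argmax <- function(hm, floor = 0.05, label = NA_character_) {
  m <- unclass_grid(hm)
  peak <- max(m)
  if (!is.finite(peak) || peak < floor) {
    return(not_detected("keypoint peak below detection floor"))
  }
  hits <- which(m == peak, arr.ind = TRUE)
  # lowest y then lowest x: order rows by (row, col)
  hit <- hits[order(hits[, 1], hits[, 2])[1], ]
  keypoint(hit[2] - 1, hit[1] - 1, label, min(max(peak, 0), 1))
}

#' Decode a keypoint by least-squares Gaussian fitting
#'
#' Fits an isotropic Gaussian (amplitude, center, sigma) to the window
#' around the argmax, recovering a sub-pixel center; used when predicted
#' heatmaps show strong local intensity variation. Falls back to the
#' argmax coordinate if the fit fails to converge or drifts by more than
#' the window radius.
#'
#' @param hm A `kp_heatmap`.
#' @param window Window radius in px (default `3 * sigma` of the heatmap,
#'   or 18 when unknown).
#' @param floor Detection floor as in [decode_keypoint_argmax()].
#' @param label Label to attach.
#' @return A [keypoint()] or [not_detected()].
#' @export
decode_keypoint_fit <- function(hm, window = NULL, floor = 0.05,
                                label = NA_character_) {
  am <- decode_keypoint_argmax(hm, floor = floor, label = label)
  if (!is_detected(am)) return(am)
  m <- unclass_grid(hm)
  sigma0 <- attr(hm, "sigma")
  if (is.null(sigma0) || !is.finite(sigma0)) sigma0 <- 6
  if (is.null(window)) window <- 3 * sigma0
  H <- nrow(m); W <- ncol(m)
  xs <- max(0, round(am$x - window)):min(W - 1, round(am$x + window))
  ys <- max(0, round(am$y - window)):min(H - 1, round(am$y + window))
  d <- data.frame(x = rep(xs, each = length(ys)),
                  y = rep(ys, times = length(xs)))
  d$v <- m[cbind(d$y + 1, d$x + 1)]
  if (sd(d$v) == 0) return(am)  # flat window: nothing to fit
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ A * exp(-((x - cx)^2 + (y - cy)^2) / (2 * s^2)), data = d,
      start = list(A = am$confidence, cx = am$x, cy = am$y, s = sigma0),
      lower = c(A = 0, cx = -Inf, cy = -Inf, s = 0.3),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(am)
  p <- coef(fit)
  if (!all(is.finite(p)) || abs(p["cx"] - am$x) > window ||
      abs(p["cy"] - am$y) > window) {
    return(am)
  }
  keypoint(p[["cx"]], p[["cy"]], label, min(max(p[["A"]], 0), 1))
}

#' Decode a line heatmap into a polyline
#'
#' Pixels with likelihood at or above the one-sigma level `exp(-0.5)` form
#' a weighted point cloud; points are ordered by projection onto the
#' cloud's principal axis, aggregated, and interpolated with smoothing
#' parametric splines; `n_samples` points equidistant in arc length are
#' returned.
#'
#' @param hm A `kp_heatmap` of kind `"line"`.
#' @param n_samples Number of output vertices (default 50).
#' @param threshold Selection threshold on the likelihood
#'   (default `exp(-0.5)`).
#' @param spar Smoothing parameter passed to [stats::smooth.spline()]
#'   (`NULL` = GCV choice).
#' @param label Label to attach.
#' @return A [polyline()] or [not_detected()].
#' @export
decode_line <- function(hm, n_samples = 50, threshold = exp(-0.5),
                        spar = NULL, label = NA_character_) {
  m <- unclass_grid(hm)
  sel <- which(m >= threshold, arr.ind = TRUE)
  if (nrow(sel) < 4) return(not_detected("too few line points above threshold"))
  w <- m[sel]
  xy <- cbind(x = sel[, 2] - 1, y = sel[, 1] - 1)
  ctr <- colSums(xy * w) / sum(w)
  cc <- sweep(xy, 2, ctr)
  cov <- crossprod(cc * sqrt(w)) / sum(w)
  ax <- eigen(cov, symmetric = TRUE)$vectors[, 1]
  t <- as.numeric(cc %*% ax)
  o <- order(t)
  t <- t[o]; xy <- xy[o, , drop = FALSE]; w <- w[o]
  # weighted smoothing splines x(t), y(t); smooth.spline aggregates ties
  fx <- tryCatch(stats::smooth.spline(t, xy[, 1], w = w, spar = spar),
                 error = function(e) NULL)
  fy <- tryCatch(stats::smooth.spline(t, xy[, 2], w = w, spar = spar),
                 error = function(e) NULL)
  tt <- seq(min(t), max(t), length.out = max(200, 4 * n_samples))
  if (is.null(fx) || is.null(fy)) {
    # degenerate parametrization (e.g. exact ties): fall back to a straight
    # total-least-squares fit along the principal axis
    px <- ctr[1] + tt * ax[1]; py <- ctr[2] + tt * ax[2]
  } else {
    px <- stats::predict(fx, tt)$y
    py <- stats::predict(fy, tt)$y
  }
  dense <- cbind(px, py)
  s <- c(0, cumsum(sqrt(rowSums(diff(dense)^2))))
  if (max(s) <= 0) return(not_detected("degenerate line support"))
  si <- seq(0, max(s), length.out = n_samples)
  out <- cbind(stats::approx(s, dense[, 1], xout = si, ties = "ordered")$y,
               stats::approx(s, dense[, 2], xout = si, ties = "ordered")$y)
  polyline(out, label = label, closed = FALSE)
}

#' Extract closed polygons from a multi-label mask
#'
#' Per channel, connected components are traced to closed contours;
#' components smaller than `min_area_frac` of the largest are dropped; the
#' largest component becomes the structure's polygon. If two or more
#' components survive the threshold the result is flagged as fragmented
#' (a known intra-operative failure mode that cancels dependent plans).
#'
#' @param mask A `kp_mask`.
#' @param min_area_frac Fraction of the largest component below which
#'   components are discarded (default 0.01).
#' @return Named list per channel: either a [polygon_region()] (with
#'   attribute `fragmented`) or [not_detected()].
#' @export
mask_to_polygons <- function(mask, min_area_frac = 0.01) {
  out <- list()
  for (lab in names(mask$channels)) {
    ch <- mask$channels[[lab]]
    if (sum(ch) == 0) {
      out[[lab]] <- not_detected("empty segmentation channel")
      next
    }
    # EBImage images are (x, y) indexed; transpose our (row=y, col=x) grid
    lbl <- EBImage::bwlabel(t(ch))
    areas <- tabulate(as.integer(lbl))
    keep <- which(areas >= min_area_frac * max(areas))
    main <- which.max(areas)
    oc <- EBImage::ocontour(lbl)[[main]]
    if (nrow(oc) < 3) {
      out[[lab]] <- not_detected("contour degenerate")
      next
    }
    # ocontour traces border pixel centers; offset outward by half a pixel
    # so the polygon encloses the full pixel area (center convention)
    ring <- offset_ring(oc, 0.5)
    poly <- polygon_region(ring, label = lab)
    attr(poly, "fragmented") <- length(keep) >= 2
    out[[lab]] <- poly
  }
  out
}

#' Reduce a contour to a weighted subsection
#'
#' Interprets a heatmap as a weighted mask over a structure's contour: the
#' contour points with likelihood at or above `threshold` form the
#' subsection, and the longest contiguous run along the (closed) contour is
#' returned as an open polyline. Used e.g. to isolate the posterior cortex
#' of the femoral shaft from the full femur outline.
#'
#' @param region A [polygon_region()] whose outer ring is the contour.
#' @param weight_hm A `kp_heatmap` in the same frame.
#' @param threshold Minimum likelihood (default `exp(-0.5)`).
#' @param resample_px Contour resampling step in px before weighting
#'   (default 1).
#' @param label Label for the resulting polyline.
#' @return A [polyline()] or [not_detected()].
#' @export
contour_subsection <- function(region, weight_hm, threshold = exp(-0.5),
                               resample_px = 1, label = NA_character_) {
  m <- unclass_grid(weight_hm)
  H <- nrow(m); W <- ncol(m)
  ring <- resample_ring(region$outer, resample_px)
  xi <- round(ring[, 1]) + 1; yi <- round(ring[, 2]) + 1
  ok <- xi >= 1 & xi <= W & yi >= 1 & yi <= H
  w <- rep(0, nrow(ring))
  w[ok] <- m[cbind(yi[ok], xi[ok])]
  sel <- w >= threshold
  if (!any(sel)) return(not_detected("no contour points above threshold"))
  if (all(sel)) {
    return(polyline(ring, label = label, closed = FALSE))
  }
  # longest contiguous circular run of selected points
  n <- length(sel)
  sel2 <- c(sel, sel)
  best_len <- 0; best_start <- 1; run <- 0
  for (i in seq_len(2 * n)) {
    if (sel2[i]) {
      run <- run + 1
      if (run > best_len && i - run + 1 <= n) {
        best_len <- run; best_start <- i - run + 1
      }
    } else run <- 0
  }
  best_len <- min(best_len, n)
  idx <- ((best_start - 1) + seq_len(best_len) - 1) %% n + 1
  if (best_len < 2) return(not_detected("contour subsection too short"))
  polyline(ring[idx, , drop = FALSE], label = label, closed = FALSE)
}

offset_ring <- function(ring, by = 0.5) {
  # offset a closed ring outward by `by` px using mitered edge normals
  dup <- rowSums(abs(diff(rbind(ring, ring[1, ])))) == 0
  ring <- ring[!dup, , drop = FALSE]
  n <- nrow(ring)
  if (n < 3) return(ring)
  nxt <- c(2:n, 1)
  e <- ring[nxt, ] - ring
  len <- sqrt(rowSums(e^2))
  e <- e / len
  sgn <- if (shoelace_area(ring) > 0) 1 else -1
  nrm <- cbind(sgn * e[, 2], -sgn * e[, 1])  # outward unit edge normals
  prv <- c(n, 1:(n - 1))
  m <- nrm + nrm[prv, ]
  denom <- pmax(1 + rowSums(nrm * nrm[prv, ]), 0.2)  # clamp sharp spikes
  ring + by * m / denom
}

#' Resample a closed ring to near-uniform spacing
#'
#' @param ring n x 2 ring vertex matrix (unclosed).
#' @param step Target spacing in px.
#' @return Resampled m x 2 matrix (unclosed).
#' @export
resample_ring <- function(ring, step = 0.5) {
  closed <- rbind(ring, ring[1, ])
  s <- c(0, cumsum(sqrt(rowSums(diff(closed)^2))))
  total <- max(s)
  if (total <= 0) return(ring)
  si <- seq(0, total, by = step)
  si <- si[si < total]
  cbind(stats::approx(s, closed[, 1], xout = si, ties = "ordered")$y,
        stats::approx(s, closed[, 2], xout = si, ties = "ordered")$y)
}

unclass_grid <- function(hm) {
  m <- unclass(hm)
  attributes(m) <- list(dim = dim(m))
  m
}
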