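# Evaluation metrics for detection outputs and plan targets:
# foreground/background-averaged Dice, average symmetric surface distance
# (ASSD), keypoint Euclidean distance, moment-based line centroid and
# orientation, and test-set aggregation to median + bootstrap 95% CI.

#' Foreground/background-averaged Dice coefficient
#'
#' Mean of the foreground Dice `2|A n B| / (|A| + |B|)` and the background
#' Dice computed on the complements. A side (fg or bg) that is empty in
#' both masks scores 1 by convention.
#'
#' @param pred,gt Binary matrices of equal shape.
#' @return Value in `[0, 1]`.
#' @export
dice_score <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt))) stop("dice_score: shape mismatch")
  p <- pred > 0.5; g <- gt > 0.5
  half_dice <- function(a, b) {
    s <- sum(a) + sum(b)
    if (s == 0) return(1)
    2 * sum(a & b) / s
  }
  (half_dice(p, g) + half_dice(!p, !g)) / 2
}

#' Average symmetric surface distance
#'
#' `ASSD = (sum_{x in C} d(x, C') + sum_{x' in C'} d(x', C)) / (|C| + |C'|)`
#' with `d(x, C') = min_{x'} |x - x'|`. Contours are densely resampled
#' (default spacing 0.5 px) before evaluation so the result measures the
#' curves, not the vertex placement.
#'
#' @param C,Cp Contours: n x 2 coordinate matrices, [polyline()] or
#'   [polygon_region()] objects (outer ring used, treated as closed).
#' @param spacing Resampling step in px (`NA` to use points as given).
#' @param cal Optional [calibration()] for an mm-valued result attribute.
#' @return ASSD in px (attribute `mm` when calibrated).
#' @export
assd <- function(C, Cp, spacing = 0.5, cal = NULL) {
  A <- contour_points(C, spacing)
  B <- contour_points(Cp, spacing)
  if (nrow(A) == 0 || nrow(B) == 0) stop("assd: empty contour")
  v <- cpp_assd(A, B)
  attr(v, "mm") <- unname(px_to_mm(v, cal))
  v
}

contour_points <- function(x, spacing = 0.5) {
  if (inherits(x, "kp_polygon")) {
    pts <- x$outer; closed <- TRUE
  } else if (inherits(x, "kp_polyline")) {
    pts <- x$points; closed <- x$closed
  } else {
    pts <- as.matrix(x); closed <- FALSE
  }
  if (is.na(spacing)) return(pts)
  if (closed) return(resample_ring(pts, spacing))
  s <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  if (max(s) <= 0) return(pts[1, , drop = FALSE])
  si <- seq(0, max(s), by = spacing)
  cbind(stats::approx(s, pts[, 1], xout = si, ties = "ordered")$y,
        stats::approx(s, pts[, 2], xout = si, ties = "ordered")$y)
}

#' Euclidean keypoint localization error
#'
#' @param pred,gt [keypoint()] objects in the same frame.
#' @param cal Optional [calibration()].
#' @return Distance in px; attribute `mm` when calibrated.
#' @export
keypoint_ed <- function(pred, gt, cal = NULL) {
  d <- sqrt((pred$x - gt$x)^2 + (pred$y - gt$y)^2)
  attr(d, "mm") <- unname(px_to_mm(d, cal))
  d
}

#' Centroid and orientation of a line heatmap via raw image moments
#'
#' The heatmap is first truncated at the two-sigma likelihood level
#' `exp(-2)` to suppress outliers; the centroid is `(M10/M00, M01/M00)`
#' and the orientation `gamma = 0.5 * atan2(2 mu'11, mu'20 - mu'02)` from
#' the central second moments, reported in degrees in `(-90, 90]`.
#'
#' @param hm A `kp_heatmap` (or matrix).
#' @param threshold Truncation level (default `exp(-2)`).
#' @return List with `centroid` (x, y), `angle_deg`, and `degenerate`
#'   (`TRUE` for isotropic mass where orientation is undefined), or
#'   [not_detected()] for zero mass.
#' @export
line_moments <- function(hm, threshold = exp(-2)) {
  m <- unclass_grid(hm)
  m[m < threshold] <- 0
  M00 <- sum(m)
  if (M00 <= 0) return(not_detected("zero mass after truncation"))
  H <- nrow(m); W <- ncol(m)
  xs <- (seq_len(W) - 1); ys <- (seq_len(H) - 1)
  cx <- sum(colSums(m) * xs) / M00
  cy <- sum(rowSums(m) * ys) / M00
  mu20 <- sum(colSums(m) * xs^2) / M00 - cx^2
  mu02 <- sum(rowSums(m) * ys^2) / M00 - cy^2
  mu11 <- as.numeric(ys %*% m %*% xs) / M00 - cx * cy
  degenerate <- abs(mu20 - mu02) < 1e-9 && abs(mu11) < 1e-9
  ang <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  if (ang <= -90) ang <- ang + 180
  list(centroid = c(x = cx, y = cy), angle_deg = ang, degenerate = degenerate)
}

#' Undirected angular difference in degrees
#'
#' @param a,b Angles in degrees (any range).
#' @return Difference folded into `[0, 90]`.
#' @export
angle_diff <- function(a, b) {
  d <- (a - b) %% 180
  min(d, 180 - d)
}

#' Aggregate per-sample metrics over a test set
#'
#' Compares matched prediction/ground-truth feature sets sample by sample
#' and aggregates each metric to the median with a seeded percentile
#' bootstrap 95% CI. Cancelled plans are excluded from the distance
#' statistics and counted separately.
#'
#' @param per_sample A tibble/data.frame with columns `sample`, `metric`,
#'   `value` (px or degrees; `NA` for cancelled plans).
#' @param n_boot Bootstrap resamples (default 10000).
#' @param seed RNG seed for the bootstrap.
#' @param cal Optional [calibration()]; adds an mm column for px metrics.
#' @return A tibble: metric, n, cancelled, median, ci_lo, ci_hi (+ mm
#'   columns when calibrated).
#' @export
evaluate_testset <- function(per_sample, n_boot = 10000, seed = 1,
                             cal = NULL) {
  stopifnot(all(c("sample", "metric", "value") %in% names(per_sample)))
  metrics <- unique(per_sample$metric)
  rows <- lapply(metrics, function(mt) {
    v <- per_sample$value[per_sample$metric == mt]
    cancelled <- sum(is.na(v))
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      return(tibble::tibble(metric = mt, n = 0L, cancelled = cancelled,
                            median = NA_real_, ci_lo = NA_real_,
                            ci_hi = NA_real_))
    }
    med <- median(v)
    if (length(v) == 1) {
      ci <- c(med, med)
    } else {
      boots <- with_local_seed(seed, {
        idx <- matrix(sample.int(length(v), length(v) * n_boot,
                                 replace = TRUE), nrow = n_boot)
        apply(idx, 1, function(i) median(v[i]))
      })
      ci <- unname(quantile(boots, c(0.025, 0.975), type = 7))
    }
    tibble::tibble(metric = mt, n = length(v), cancelled = cancelled,
                   median = med, ci_lo = ci[1], ci_hi = ci[2])
  })
  out <- do.call(rbind, rows)
  if (!is.null(cal) && cal$source != "none") {
    px_cols <- c("median", "ci_lo", "ci_hi")
    for (cl in px_cols) out[[paste0(cl, "_mm")]] <- out[[cl]] * cal$mm_per_px
  }
  out
}

# Evaluate `expr` under a temporary seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(as.integer(seed %% .Machine$integer.max))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}
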