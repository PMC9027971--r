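# Optimization of the multi-task objective: preprocessing, coordinate-space
# augmentation, Soft-Dice+BCE / MSE losses, uniform or GradNorm task
# weighting, cyclical learning-rate schedule (Nesterov) or step-decayed
# RMSProp, and model selection by minimum unweighted composite validation
# loss.

#' Training configuration
#'
#' Defaults follow the reference protocol: batch size 2, Nesterov momentum
#' with a triangular cyclical schedule (lr 0.001-0.1, momentum 0.9-0.8,
#' full cycle 360 update iterations), L2 weight decay 5e-5, GradNorm
#' asymmetry alpha = 1. The `rmsprop_step` optimizer (intra-operative
#' protocol) uses lr 0.001 with a single x0.1 decay at `rmsprop_decay_epoch`.
#'
#' @param epochs Training epochs (reference protocol: 400 diagnostic, 500
#'   intra-operative; scale down for desk experiments).
#' @param batch_size Mini-batch size (default 2).
#' @param optimizer `"nesterov_clr"` or `"rmsprop_step"`.
#' @param lr_min,lr_max,momentum_min,momentum_max,cycle_len Cyclical
#'   schedule bounds and full cycle length in update iterations.
#' @param rmsprop_decay_epoch,rmsprop_decay_factor Step decay of the
#'   RMSProp variant.
#' @param weight_decay L2 regularization coefficient on conv weights.
#' @param weighting `"uniform"` or `"gradnorm"`.
#' @param gradnorm_alpha GradNorm asymmetry parameter.
#' @param sigma Heatmap encoding standard deviation in px.
#' @param augment Apply the online augmentation protocol (shear in
#'   `[-2, 2]` deg with p = 0.5, horizontal flip p = 0.5, rotation
#'   `[-45, 45]` deg p = 1, scale `[0.8, 1.2]` p = 1).
#' @param seed RNG seed covering shuffling and augmentation.
#' @return A `kp_train_config`.
#' @export
train_config <- function(epochs = 400, batch_size = 2,
                         optimizer = c("nesterov_clr", "rmsprop_step"),
                         lr_min = 0.001, lr_max = 0.1,
                         momentum_min = 0.8, momentum_max = 0.9,
                         cycle_len = 360, rmsprop_decay_epoch = 350,
                         rmsprop_decay_factor = 0.1,
                         weight_decay = 0.00005,
                         weighting = c("uniform", "gradnorm"),
                         gradnorm_alpha = 1, sigma = 6, augment = TRUE,
                         seed = 1) {
  optimizer <- match.arg(optimizer)
  weighting <- match.arg(weighting)
  stopifnot(lr_min < lr_max, momentum_min < momentum_max, lr_min > 0,
            momentum_min > 0, cycle_len > 0, epochs >= 1, batch_size >= 1,
            weight_decay >= 0, sigma > 0)
  structure(list(epochs = epochs, batch_size = batch_size,
                 optimizer = optimizer, lr_min = lr_min, lr_max = lr_max,
                 momentum_min = momentum_min, momentum_max = momentum_max,
                 cycle_len = cycle_len,
                 rmsprop_decay_epoch = rmsprop_decay_epoch,
                 rmsprop_decay_factor = rmsprop_decay_factor,
                 weight_decay = weight_decay, weighting = weighting,
                 gradnorm_alpha = gradnorm_alpha, sigma = sigma,
                 augment = isTRUE(augment), seed = seed),
            class = "kp_train_config")
}

#' Min-max intensity normalization
#'
#' `x~ = (x - min(x)) / (max(x) - min(x))`. A constant image cannot be
#' normalized; it maps to all zeros with a warning.
#'
#' @param img Numeric matrix or array.
#' @return Same shape, values in `[0, 1]`.
#' @export
normalize_intensity <- function(img) {
  rng <- range(img)
  if (!all(is.finite(rng))) stop("non-finite intensities")
  if (rng[2] - rng[1] <= 0) {
    warning("constant image: min-max normalization undefined, returning zeros")
    return(img * 0)
  }
  (img - rng[1]) / (rng[2] - rng[1])
}

#' Geometric preprocessing to the network resolution
#'
#' Isotropic bicubic resampling by `s = size / max(H, W)` preserving the
#' aspect ratio, zero-padded right/bottom to `size x size`. Geometry is
#' mapped in coordinate space (multiplied by `s`; no offset under
#' right/bottom padding) so no label information is lost to raster
#' interpolation. The returned transform inverts back to the original
#' frame.
#'
#' @param img `H x W` matrix.
#' @param features Optional [feature_set()] to map along.
#' @param size Target square size (default 256).
#' @return List: `image` (`size x size`), `features`, `scale`,
#'   `transform` (a `kp_transform`), `inverse` (its inverse).
#' @export
geometric_preprocess <- function(img, features = NULL, size = 256) {
  H <- nrow(img); W <- ncol(img)
  s <- size / max(H, W)
  tf <- similarity_transform(scale = s)
  if (H == size && W == size) {
    out <- img
  } else {
    # output pixel (x, y) samples source (x / s, y / s)
    M <- c(1 / s, 0, 0, 0, 1 / s, 0)
    out <- cpp_warp_affine_bicubic(img, M, size, size)
  }
  list(image = out, features = map_features(features, tf), scale = s,
       transform = tf, inverse = invert_transform(tf))
}

map_features <- function(features, tf) {
  if (is.null(features)) return(NULL)
  mp <- function(lst) lapply(lst, function(f) {
    if (is_detected(f)) apply_similarity(f, tf) else f
  })
  feature_set(keypoints = mp(features$keypoints), lines = mp(features$lines),
              regions = mp(features$regions),
              provenance = features$provenance)
}

shear_transform <- function(deg) {
  structure(list(A = matrix(c(1, 0, tan(deg * pi / 180), 1), 2, 2),
                 t = c(0, 0), mirror = FALSE),
            class = "kp_transform")
}

#' Online augmentation of an image + geometry sample
#'
#' Draws one random spatial transform (shear, horizontal flip, in-plane
#' rotation, scaling, centered on the image) and applies it to the raster
#' by bicubic warping and to the ground-truth geometry exactly in
#' coordinate space. Spatial encodings must be generated only afterwards.
#'
#' @param sample List with `image` (matrix) and `features`
#'   ([feature_set()]).
#' @param shear_range,rotation_range,scale_range,flip_prob,shear_prob
#'   Protocol parameters (defaults as in [train_config()]).
#' @return Augmented sample (same structure, plus `transform`).
#' @export
augment_sample <- function(sample, shear_range = c(-2, 2),
                           rotation_range = c(-45, 45),
                           scale_range = c(0.8, 1.2), flip_prob = 0.5,
                           shear_prob = 0.5) {
  H <- nrow(sample$image); W <- ncol(sample$image)
  ctr <- c((W - 1) / 2, (H - 1) / 2)
  tf <- similarity_transform()  # identity
  if (runif(1) < flip_prob) {
    # mirror about the vertical image center line: x -> (W - 1) - x
    tf <- compose_transform(similarity_transform(tx = W - 1, mirror = TRUE),
                            tf)
  }
  if (runif(1) < shear_prob) {
    sh <- compose_transform(
      compose_transform(similarity_transform(tx = ctr[1], ty = ctr[2]),
                        shear_transform(runif(1, shear_range[1],
                                              shear_range[2]))),
      similarity_transform(tx = -ctr[1], ty = -ctr[2]))
    tf <- compose_transform(sh, tf)
  }
  rs <- compose_transform(
    compose_transform(similarity_transform(tx = ctr[1], ty = ctr[2]),
                      similarity_transform(
                        angle_deg = runif(1, rotation_range[1],
                                          rotation_range[2]),
                        scale = runif(1, scale_range[1], scale_range[2]))),
    similarity_transform(tx = -ctr[1], ty = -ctr[2]))
  tf <- compose_transform(rs, tf)
  inv <- invert_transform(tf)
  M <- c(inv$A[1, 1], inv$A[1, 2], inv$t[1],
         inv$A[2, 1], inv$A[2, 2], inv$t[2])
  img <- cpp_warp_affine_bicubic(sample$image, M, H, W)
  list(image = img, features = map_features(sample$features, tf),
       transform = tf)
}

#' Per-task loss
#'
#' Segmentation: `(1 - softDice) + BCE`, each averaged over channels
#' (`pred` holds probabilities; soft-Dice uses +1 smoothing in numerator
#' and denominator). Keypoint/line: mean squared error over all pixels and
#' channels.
#'
#' @param task A [task_spec()].
#' @param pred,target Arrays of matching shape (`H x W [x C [x N]]`).
#' @return Non-negative scalar.
#' @export
task_loss <- function(task, pred, target) {
  if (!all(dim(pred) == dim(target))) stop("task_loss: shape mismatch")
  if (task$kind == "segmentation") {
    ch <- channel_split(pred, target)
    sdice <- mean(vapply(ch, function(pt) {
      1 - (2 * sum(pt$p * pt$t) + 1) / (sum(pt$p) + sum(pt$t) + 1)
    }, numeric(1)))
    bce <- mean(vapply(ch, function(pt) {
      p <- pmin(pmax(pt$p, 1e-12), 1 - 1e-12)
      mean(-pt$t * log(p) - (1 - pt$t) * log(1 - p))
    }, numeric(1)))
    sdice + bce
  } else {
    mean((pred - target)^2)
  }
}

channel_split <- function(pred, target) {
  d <- dim(pred)
  if (is.null(d) || length(d) == 2) {
    return(list(list(p = pred, t = target)))
  }
  C <- d[3]
  lapply(seq_len(C), function(c) {
    if (length(d) == 3) list(p = pred[, , c], t = target[, , c])
    else list(p = pred[, , c, , drop = FALSE], t = target[, , c, , drop = FALSE])
  })
}

# Loss + gradient w.r.t. raw network output (logits for segmentation).
task_loss_grad <- function(task, z, target) {
  d <- dim(z); C <- d[3]; N <- d[4]; HW <- d[1] * d[2]
  if (task$kind == "segmentation") {
    p <- 1 / (1 + exp(-z))
    g <- array(0, d)
    sdice <- 0; bce <- 0
    for (n in seq_len(N)) for (c in seq_len(C)) {
      pc <- p[, , c, n]; tc <- target[, , c, n]
      num <- 2 * sum(pc * tc) + 1
      den <- sum(pc) + sum(tc) + 1
      sdice <- sdice + (1 - num / den)
      dsdice_dp <- -(2 * tc * den - num) / den^2
      pcl <- pmin(pmax(pc, 1e-12), 1 - 1e-12)
      bce <- bce + mean(-tc * log(pcl) - (1 - tc) * log(1 - pcl))
      dbce_dz <- (pc - tc) / HW
      g[, , c, n] <- (dsdice_dp * pc * (1 - pc) + dbce_dz) / (C * N)
    }
    list(loss = (sdice + bce) / (C * N), grad = g)
  } else {
    diff <- z - target
    list(loss = mean(diff^2), grad = 2 * diff / length(diff))
  }
}

#' Weighted composite loss
#'
#' `L = sum_t w_t L_t`.
#'
#' @param losses Named numeric vector of per-task losses.
#' @param weights Named numeric vector of positive task weights covering
#'   the same tasks.
#' @return Scalar.
#' @export
composite_loss <- function(losses, weights) {
  missing <- setdiff(names(losses), names(weights))
  if (length(missing)) {
    stop("missing weight for task(s): ", paste(missing, collapse = ", "))
  }
  sum(unlist(losses) * weights[names(losses)])
}

#' One GradNorm task-weight update
#'
#' Takes one gradient step on the GradNorm objective
#' `sum_t | G_t - Gbar * r_t^alpha |`, where `G_t = w_t * g_t` is the
#' gradient norm of the weighted task loss at the designated shared layer,
#' `r_t` the relative inverse training rate `(L_t / L_t(0))` normalized by
#' its task mean, and `Gbar` the mean gradient norm (both treated as
#' constants in the step). Weights are then renormalized to sum to the
#' number of tasks and kept positive.
#'
#' @param weights Named positive weights (sum T on entry).
#' @param current_losses,initial_losses Named per-task losses now and at
#'   the reference step.
#' @param shared_layer_grad_norms Named `G_t` values (weighted norms).
#' @param alpha Asymmetry parameter (default 1).
#' @param lr Step size on the weights.
#' @return Updated named weights (sum = number of tasks).
#' @export
gradnorm_step <- function(weights, current_losses, initial_losses,
                          shared_layer_grad_norms, alpha = 1, lr = 0.025) {
  tn <- names(weights)
  TT <- length(tn)
  G <- unlist(shared_layer_grad_norms)[tn]
  if (!all(is.finite(G))) {
    warning("non-finite gradient norms: skipping GradNorm update")
    return(weights)
  }
  Lr <- unlist(current_losses)[tn] / pmax(unlist(initial_losses)[tn], 1e-12)
  r <- Lr / mean(Lr)
  target <- mean(G) * r^alpha
  g_unweighted <- G / weights
  dw <- sign(G - target) * g_unweighted
  w <- weights - lr * dw
  w <- pmax(w, 1e-3)
  w * TT / sum(w)
}

#' Cyclical learning-rate schedule
#'
#' Triangular wave: the learning rate rises linearly from `lr_min` to
#' `lr_max` over the first half cycle and falls back over the second;
#' momentum anneals inversely (high when the learning rate is low).
#'
#' @param iteration Update iteration (0-based).
#' @param cfg A [train_config()].
#' @return List with `lr` and `momentum`.
#' @export
clr_schedule <- function(iteration, cfg = train_config()) {
  stopifnot(iteration >= 0)
  half <- cfg$cycle_len / 2
  phase <- iteration %% cfg$cycle_len
  frac <- 1 - abs(phase / half - 1)  # 0 at cycle start, 1 at midpoint
  list(lr = cfg$lr_min + frac * (cfg$lr_max - cfg$lr_min),
       momentum = cfg$momentum_max - frac * (cfg$momentum_max - cfg$momentum_min))
}

encode_targets <- function(features, tasks, shape, sigma) {
  out <- list()
  for (t in tasks) {
    a <- array(0, c(shape, t$n_channels))
    for (i in seq_along(t$channels)) {
      lab <- t$channels[i]
      if (t$kind == "segmentation") {
        rg <- features$regions[[lab]]
        if (!is.null(rg) && is_detected(rg)) {
          a[, , i] <- rasterize_polygon(rg, shape[1], shape[2])
        }
      } else if (t$kind == "keypoint") {
        kp <- features$keypoints[[lab]]
        if (!is.null(kp) && is_detected(kp) && kp$x >= 0 && kp$x < shape[2] &&
            kp$y >= 0 && kp$y < shape[1]) {
          a[, , i] <- encode_keypoint(kp, shape, sigma)
        }
      } else {
        ln <- features$lines[[lab]]
        if (!is.null(ln) && is_detected(ln)) {
          a[, , i] <- cpp_line_heatmap(ln$points, shape[1], shape[2], sigma)
        }
      }
    }
    out[[t$name]] <- a
  }
  out
}

prepare_batch <- function(samples, tasks, input_size, sigma, augment) {
  N <- length(samples)
  x <- array(0, c(input_size, input_size, 1, N))
  targets <- lapply(tasks, function(t) {
    array(0, c(input_size, input_size, t$n_channels, N))
  })
  names(targets) <- vapply(tasks, `[[`, character(1), "name")
  for (i in seq_len(N)) {
    sm <- samples[[i]]
    if (augment) sm <- augment_sample(sm)
    pp <- geometric_preprocess(sm$image, sm$features, input_size)
    x[, , 1, i] <- normalize_intensity(pp$image)
    enc <- encode_targets(pp$features, tasks, c(input_size, input_size),
                          sigma)
    for (tn in names(enc)) targets[[tn]][, , , i] <- enc[[tn]]
  }
  list(x = x, targets = targets)
}

sgd_update <- function(model, grads, state, lr, momentum, cfg) {
  ps <- model$params
  for (nm in ls(grads)) {
    g <- grads[[nm]]
    if (cfg$weight_decay > 0 && endsWith(nm, ".w")) {
      g <- g + cfg$weight_decay * ps[[nm]]
    }
    if (cfg$optimizer == "nesterov_clr") {
      v <- state[[nm]]
      if (is.null(v)) v <- g * 0
      v <- momentum * v + g
      state[[nm]] <- v
      ps[[nm]] <- ps[[nm]] - lr * (g + momentum * v)
    } else {
      s <- state[[nm]]
      if (is.null(s)) s <- g * 0
      s <- 0.99 * s + 0.01 * g * g
      state[[nm]] <- s
      ps[[nm]] <- ps[[nm]] - lr * g / (sqrt(s) + 1e-8)
    }
  }
}

#' Train a multi-task model
#'
#' Runs the full optimization loop (augment -> preprocess -> encode ->
#' forward -> per-task losses -> weighting -> Nesterov/RMSProp update with
#' L2 decay), evaluating the unweighted composite loss `sum_t L_t` on the
#' validation split after every epoch and returning the checkpoint of the
#' minimizing epoch. Fully reproducible for a fixed `cfg$seed`.
#'
#' @param model A [build_model()] result (modified in place; the returned
#'   `model` is the best-epoch copy).
#' @param dataset List with `samples` (each `list(image, features)`),
#'   `train` and `val` index vectors.
#' @param cfg A [train_config()].
#' @return A `kp_train_fit`: `model` (best checkpoint), `final_model`,
#'   `history` (tibble), `best_epoch`, `weights`, `cfg`.
#' @export
train <- function(model, dataset, cfg = train_config()) {
  if (length(dataset$train) == 0 || length(dataset$val) == 0) {
    stop("empty train or validation split")
  }
  tasks <- model$config$tasks
  tn <- names(tasks)
  with_local_seed(cfg$seed, {
    weights <- stats::setNames(rep(1, length(tn)), tn)
    state <- new.env(parent = emptyenv())
    L0 <- NULL
    iter <- 0
    history <- vector("list", cfg$epochs)
    best_val <- Inf; best_epoch <- NA_integer_; best <- NULL
    for (epoch in seq_len(cfg$epochs)) {
      idx <- sample(dataset$train)
      nb <- ceiling(length(idx) / cfg$batch_size)
      train_losses <- stats::setNames(numeric(length(tn)), tn)
      for (b in seq_len(nb)) {
        take <- idx[((b - 1) * cfg$batch_size + 1):min(b * cfg$batch_size,
                                                       length(idx))]
        batch <- prepare_batch(dataset$samples[take], tasks,
                               model$config$input_size, cfg$sigma,
                               cfg$augment)
        fw <- model_forward(model, batch$x, training = TRUE)
        losses <- stats::setNames(numeric(length(tn)), tn)
        d_outs <- list()
        for (t in tasks) {
          lg <- task_loss_grad(t, fw$outputs[[t$name]],
                               batch$targets[[t$name]])
          losses[t$name] <- lg$loss
          d_outs[[t$name]] <- lg$grad * weights[t$name]
        }
        use_gn <- cfg$weighting == "gradnorm" &&
          model$config$topology != "single_task"
        bw <- model_backward(model, fw$cache, d_outs,
                             shared_norms = use_gn)
        sched <- if (cfg$optimizer == "nesterov_clr") {
          clr_schedule(iter, cfg)
        } else {
          decay <- if (epoch > cfg$rmsprop_decay_epoch) {
            cfg$rmsprop_decay_factor
          } else 1
          list(lr = cfg$lr_min * decay, momentum = 0)
        }
        sgd_update(model, bw$grads, state, sched$lr, sched$momentum, cfg)
        if (use_gn) {
          if (is.null(L0)) {
            L0 <- losses  # recorded after the first optimization step
          } else {
            weights <- gradnorm_step(weights, losses, L0, bw$shared_norms,
                                     alpha = cfg$gradnorm_alpha)
          }
        }
        train_losses <- train_losses + losses
        iter <- iter + 1
      }
      train_losses <- train_losses / nb
      val <- validate(model, dataset, tasks, cfg)
      if (sum(val) < best_val) {
        best_val <- sum(val); best_epoch <- epoch
        best <- clone_model(model)
      }
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, task = tn, train_loss = unname(train_losses),
        val_loss = unname(val), weight = unname(weights[tn]),
        lr = if (cfg$optimizer == "nesterov_clr") {
          clr_schedule(iter - 1, cfg)$lr
        } else cfg$lr_min,
        val_total = sum(val))
    }
    structure(list(model = best, final_model = model,
                   history = do.call(rbind, history),
                   best_epoch = best_epoch, best_val_loss = best_val,
                   weights = weights, cfg = cfg),
              class = "kp_train_fit")
  })
}

validate <- function(model, dataset, tasks, cfg) {
  tn <- names(tasks)
  totals <- stats::setNames(numeric(length(tn)), tn)
  n <- 0
  idx <- dataset$val
  bs <- cfg$batch_size
  for (b in seq_len(ceiling(length(idx) / bs))) {
    take <- idx[((b - 1) * bs + 1):min(b * bs, length(idx))]
    batch <- prepare_batch(dataset$samples[take], tasks,
                           model$config$input_size, cfg$sigma,
                           augment = FALSE)
    fw <- model_forward(model, batch$x, training = FALSE)
    for (t in tasks) {
      lg <- task_loss_grad(t, fw$outputs[[t$name]], batch$targets[[t$name]])
      totals[t$name] <- totals[t$name] + lg$loss * length(take)
    }
    n <- n + length(take)
  }
  totals / n
}

#' @export
print.kp_train_fit <- function(x, ...) {
  cat(sprintf("<training fit> %d epochs, best epoch %d (val loss %.4f), weighting %s\n",
              max(x$history$epoch), x$best_epoch, x$best_val_loss,
              x$cfg$weighting))
  invisible(x)
}

#' @importFrom tibble tibble
#' @export
tidy.kp_train_fit <- function(x, ...) x$history

#' @export
glance.kp_train_fit <- function(x, ...) {
  tibble::tibble(epochs = max(x$history$epoch), best_epoch = x$best_epoch,
                 best_val_loss = x$best_val_loss,
                 weighting = x$cfg$weighting,
                 optimizer = x$cfg$optimizer)
}

#' Tidy a fitted training run
#' @param x Object.
#' @param ... Unused.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row summary of a fitted training run
#' @param x Object.
#' @param ... Unused.
#' @export
glance <- function(x, ...) UseMethod("glance")
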