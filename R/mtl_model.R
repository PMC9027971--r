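# Stage A: hourglass encoder-decoder with configurable parameter-sharing
# topology. All convolution blocks are residual pre-activation bottleneck
# stacks with a constant channel count across scales; skip connections are
# parameterized (a bottleneck on each skip path). Topologies:
#   single_task  - one independent encoder-decoder + head per task
#   multi_head   - shared encoder and decoder, per-task 1x1 heads
#   multi_decoder- shared encoder, per-task decoders + heads

#' Task specification
#'
#' @param name Unique task name.
#' @param kind `"segmentation"`, `"keypoint"` or `"line"`; fixes the loss
#'   (Soft-Dice + BCE for segmentation, MSE for heatmap regression).
#' @param channels Character vector of output channel labels (e.g.
#'   `c("S1", "S2")`); its length is the number of output maps.
#' @return A `kp_task` object.
#' @export
task_spec <- function(name, kind = c("segmentation", "keypoint", "line"),
                      channels) {
  kind <- match.arg(kind)
  stopifnot(length(channels) >= 1)
  structure(list(name = name, kind = kind,
                 channels = as.character(channels),
                 n_channels = length(channels)),
            class = "kp_task")
}

#' Model configuration
#'
#' @param tasks List of [task_spec()] with unique names.
#' @param topology Parameter-sharing topology.
#' @param n_features Constant channel count throughout the hourglass
#'   (default 128).
#' @param depth Number of down/up-sampling levels (default 4);
#'   `input_size` must be divisible by `2^depth`.
#' @param input_size Square input resolution in px (default 256).
#' @return A `kp_model_config`.
#' @export
model_config <- function(tasks,
                         topology = c("multi_head", "multi_decoder",
                                      "single_task"),
                         n_features = 128, depth = 4, input_size = 256) {
  topology <- match.arg(topology)
  stopifnot(depth >= 1, n_features >= 2)
  if (input_size %% 2^depth != 0) {
    stop(sprintf("input_size %d is not divisible by 2^%d", input_size, depth))
  }
  nms <- vapply(tasks, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("task names must be unique")
  structure(list(tasks = stats::setNames(tasks, nms), topology = topology,
                 n_features = as.integer(n_features),
                 depth = as.integer(depth),
                 input_size = as.integer(input_size)),
            class = "kp_model_config")
}

enc_init <- function(ps, bufs, p, F, depth) {
  nn_init_conv(ps, paste0(p, "stem"), 3, 3, 1, F)
  for (l in seq_len(depth)) {
    bottleneck_init(ps, bufs, paste0(p, "skip", l), F)
    bottleneck_init(ps, bufs, paste0(p, "down", l), F)
  }
  bottleneck_init(ps, bufs, paste0(p, "bottom"), F)
}

dec_init <- function(ps, bufs, p, F, depth) {
  for (l in seq_len(depth)) bottleneck_init(ps, bufs, paste0(p, "up", l), F)
  nn_init_bn(ps, bufs, paste0(p, "neckbn"), F)
  nn_init_conv(ps, paste0(p, "neck"), 3, 3, F, F)
}

head_init <- function(ps, bufs, p, F, n_ch) {
  nn_init_conv(ps, paste0(p, "head"), 1, 1, F, n_ch)
}

#' Build a multi-task hourglass model
#'
#' @param config A [model_config()].
#' @param seed Seed for weight initialization.
#' @return A `kp_model` (parameters and batch-norm buffers in
#'   environments, so training updates in place).
#' @export
build_model <- function(config, seed = 1) {
  stopifnot(inherits(config, "kp_model_config"))
  ps <- new.env(parent = emptyenv())
  bufs <- new.env(parent = emptyenv())
  F <- config$n_features; depth <- config$depth
  with_local_seed(seed, {
    switch(config$topology,
      single_task = for (t in config$tasks) {
        p <- paste0("st.", t$name, ".")
        enc_init(ps, bufs, p, F, depth)
        dec_init(ps, bufs, p, F, depth)
        head_init(ps, bufs, paste0(p, t$name, "."), F, t$n_channels)
      },
      multi_head = {
        enc_init(ps, bufs, "sh.", F, depth)
        dec_init(ps, bufs, "sh.", F, depth)
        for (t in config$tasks) {
          head_init(ps, bufs, paste0("hd.", t$name, "."), F,
                    t$n_channels)
        }
      },
      multi_decoder = {
        enc_init(ps, bufs, "sh.", F, depth)
        for (t in config$tasks) {
          dec_init(ps, bufs, paste0("dec.", t$name, "."), F, depth)
          head_init(ps, bufs, paste0("hd.", t$name, "."), F,
                    t$n_channels)
        }
      })
  })
  structure(list(config = config, params = ps, buffers = bufs),
            class = "kp_model")
}

#' Number of trainable parameters
#'
#' @param model A `kp_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(ls(model$params), function(nm) length(model$params[[nm]]),
             numeric(1)))
}

enc_forward <- function(ps, bufs, p, x, depth, training) {
  st <- conv_f(ps, paste0(p, "stem"), x)
  cur <- st$y
  skips <- vector("list", depth); cskip <- vector("list", depth)
  cpool <- vector("list", depth); cdown <- vector("list", depth)
  for (l in seq_len(depth)) {
    sk <- bottleneck_f(ps, bufs, paste0(p, "skip", l), cur, training)
    skips[[l]] <- sk$y; cskip[[l]] <- sk$cache
    pl <- pool_f(cur); cpool[[l]] <- pl$cache
    dn <- bottleneck_f(ps, bufs, paste0(p, "down", l), pl$y, training)
    cur <- dn$y; cdown[[l]] <- dn$cache
  }
  bt <- bottleneck_f(ps, bufs, paste0(p, "bottom"), cur, training)
  list(bottom = bt$y, skips = skips,
       cache = list(p = p, stem = st$cache, skip = cskip, pool = cpool,
                    down = cdown, bottom = bt$cache, depth = depth))
}

enc_backward <- function(ps, gr, cache, d_bottom, d_skips) {
  p <- cache$p; depth <- cache$depth
  d <- bottleneck_b(ps, gr, cache$bottom, d_bottom)
  for (l in rev(seq_len(depth))) {
    d <- bottleneck_b(ps, gr, cache$down[[l]], d)
    d <- pool_b(cache$pool[[l]], d)
    d <- d + bottleneck_b(ps, gr, cache$skip[[l]], d_skips[[l]])
  }
  conv_b(ps, gr, cache$stem, d)
}

dec_forward <- function(ps, bufs, p, bottom, skips, depth, training) {
  cur <- bottom
  cup <- vector("list", depth); cups <- vector("list", depth)
  for (l in rev(seq_len(depth))) {
    up <- upsample_f(cur); cups[[l]] <- up$cache
    ub <- bottleneck_f(ps, bufs, paste0(p, "up", l), up$y + skips[[l]],
                       training)
    cur <- ub$y; cup[[l]] <- ub$cache
  }
  nb <- bn_f(ps, bufs, paste0(p, "neckbn"), cur, training)
  nr <- relu_f(nb$y)
  nc <- conv_f(ps, paste0(p, "neck"), nr$y)
  list(z = nc$y,
       cache = list(p = p, up = cup, ups = cups, neckbn = nb$cache,
                    neckrelu = nr$cache, neck = nc$cache, depth = depth))
}

dec_backward <- function(ps, gr, cache, dz) {
  depth <- cache$depth
  d <- conv_b(ps, gr, cache$neck, dz)
  d <- relu_b(cache$neckrelu, d)
  d <- bn_b(ps, gr, cache$neckbn, d)
  d_skips <- vector("list", depth)
  for (l in seq_len(depth)) {
    d <- bottleneck_b(ps, gr, cache$up[[l]], d)
    d_skips[[l]] <- d
    d <- upsample_b(cache$ups[[l]], d)
  }
  list(d_bottom = d, d_skips = d_skips)
}

head_forward <- function(ps, bufs, p, z, training) {
  hr <- relu_f(z)
  hc <- conv_f(ps, paste0(p, "head"), hr$y)
  list(y = hc$y, cache = list(relu = hr$cache, conv = hc$cache))
}

head_backward <- function(ps, gr, cache, dy) {
  d <- conv_b(ps, gr, cache$conv, dy)
  relu_b(cache$relu, d)
}

model_forward <- function(model, x, training = FALSE) {
  cfg <- model$config; ps <- model$params; bufs <- model$buffers
  depth <- cfg$depth
  outs <- list(); cache <- list(topology = cfg$topology)
  if (cfg$topology == "single_task") {
    cache$tasks <- list()
    for (t in cfg$tasks) {
      p <- paste0("st.", t$name, ".")
      enc <- enc_forward(ps, bufs, p, x, depth, training)
      dec <- dec_forward(ps, bufs, p, enc$bottom, enc$skips, depth, training)
      hd <- head_forward(ps, bufs, paste0(p, t$name, "."), dec$z,
                         training)
      outs[[t$name]] <- hd$y
      cache$tasks[[t$name]] <- list(enc = enc$cache, dec = dec$cache,
                                    head = hd$cache)
    }
  } else if (cfg$topology == "multi_head") {
    enc <- enc_forward(ps, bufs, "sh.", x, depth, training)
    dec <- dec_forward(ps, bufs, "sh.", enc$bottom, enc$skips, depth,
                       training)
    cache$enc <- enc$cache; cache$dec <- dec$cache; cache$heads <- list()
    for (t in cfg$tasks) {
      hd <- head_forward(ps, bufs, paste0("hd.", t$name, "."), dec$z,
                         training)
      outs[[t$name]] <- hd$y
      cache$heads[[t$name]] <- hd$cache
    }
  } else {
    enc <- enc_forward(ps, bufs, "sh.", x, depth, training)
    cache$enc <- enc$cache; cache$dec <- list(); cache$heads <- list()
    for (t in cfg$tasks) {
      dec <- dec_forward(ps, bufs, paste0("dec.", t$name, "."), enc$bottom,
                         enc$skips, depth, training)
      hd <- head_forward(ps, bufs, paste0("hd.", t$name, "."), dec$z,
                         training)
      outs[[t$name]] <- hd$y
      cache$dec[[t$name]] <- dec$cache
      cache$heads[[t$name]] <- hd$cache
    }
  }
  list(outputs = outs, cache = cache)
}

# Backward pass. d_outs are gradients of the (already weighted) composite
# loss w.r.t. each task's raw output. When `shared_norms` is TRUE, also
# returns per-task Frobenius norms of the gradient of the weighted task
# loss at the last shared layer's weights (the shared neck convolution for
# multi_head, the bottom bottleneck's closing convolution for
# multi_decoder) — the quantity GradNorm balances.
model_backward <- function(model, cache, d_outs, shared_norms = FALSE) {
  ps <- model$params
  gr <- new.env(parent = emptyenv())
  gnorms <- NULL
  if (cache$topology == "single_task") {
    for (tn in names(cache$tasks)) {
      tc <- cache$tasks[[tn]]
      dz <- head_backward(ps, gr, tc$head, d_outs[[tn]])
      db <- dec_backward(ps, gr, tc$dec, dz)
      enc_backward(ps, gr, tc$enc, db$d_bottom, db$d_skips)
    }
  } else if (cache$topology == "multi_head") {
    dz <- NULL
    gnorms <- numeric(0)
    for (tn in names(cache$heads)) {
      dzt <- head_backward(ps, gr, cache$heads[[tn]], d_outs[[tn]])
      if (shared_norms) {
        # dzt is the task's gradient at the shared neck conv output
        wg <- cpp_conv2d_wgrad(cache$dec$neck$x, dzt, c(3L, 3L))
        gnorms[tn] <- sqrt(sum(wg^2))
      }
      dz <- if (is.null(dz)) dzt else dz + dzt
    }
    db <- dec_backward(ps, gr, cache$dec, dz)
    enc_backward(ps, gr, cache$enc, db$d_bottom, db$d_skips)
  } else {
    d_bottom <- NULL; d_skips <- NULL
    gnorms <- numeric(0)
    for (tn in names(cache$heads)) {
      dzt <- head_backward(ps, gr, cache$heads[[tn]], d_outs[[tn]])
      db <- dec_backward(ps, gr, cache$dec[[tn]], dzt)
      if (shared_norms) {
        wg <- cpp_conv2d_wgrad(cache$enc$bottom$c3$x, db$d_bottom,
                               c(1L, 1L))
        gnorms[tn] <- sqrt(sum(wg^2))
      }
      if (is.null(d_bottom)) {
        d_bottom <- db$d_bottom; d_skips <- db$d_skips
      } else {
        d_bottom <- d_bottom + db$d_bottom
        for (l in seq_along(d_skips)) {
          d_skips[[l]] <- d_skips[[l]] + db$d_skips[[l]]
        }
      }
    }
    enc_backward(ps, gr, cache$enc, d_bottom, d_skips)
  }
  list(grads = gr, shared_norms = gnorms)
}

#' Run inference on a preprocessed image
#'
#' @param model A trained `kp_model`.
#' @param image `input_size x input_size` matrix in `[0, 1]` (output of
#'   [geometric_preprocess()] + [normalize_intensity()]).
#' @return Named list task -> `H x W x C` array. Segmentation outputs are
#'   sigmoid-squashed to (0, 1); heatmap outputs are raw regression values
#'   (clamp at decoding).
#' @export
infer <- function(model, image) {
  cfg <- model$config
  if (!all(dim(image) == cfg$input_size)) {
    stop(sprintf("infer: expected %dx%d input, got %dx%d", cfg$input_size,
                 cfg$input_size, nrow(image), ncol(image)))
  }
  x <- array(image, c(dim(image), 1, 1))
  fw <- model_forward(model, x, training = FALSE)
  out <- list()
  for (t in cfg$tasks) {
    y <- fw$outputs[[t$name]][, , , 1, drop = FALSE]
    dim(y) <- dim(y)[1:3]
    dimnames(y) <- list(NULL, NULL, t$channels)
    if (t$kind == "segmentation") y <- 1 / (1 + exp(-y))
    out[[t$name]] <- y
  }
  out
}

#' Save a model checkpoint
#'
#' Single self-describing file: weights, batch-norm buffers, model config
#' (task registry included) and optional preprocessing metadata.
#'
#' @param model A `kp_model`.
#' @param path Destination file.
#' @param meta Optional list of preprocessing metadata.
#' @export
save_model <- function(model, path, meta = list()) {
  saveRDS(list(params = as.list(model$params),
               buffers = as.list(model$buffers),
               config = model$config, meta = meta), path)
}

#' Load a model checkpoint
#'
#' @param path Checkpoint file written by [save_model()].
#' @return A `kp_model` (metadata in attribute `meta`).
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  ps <- list2env(obj$params, parent = emptyenv())
  bufs <- list2env(obj$buffers, parent = emptyenv())
  structure(list(config = obj$config, params = ps, buffers = bufs),
            class = "kp_model", meta = obj$meta)
}

# Deep-copy a model (training keeps the running best checkpoint).
clone_model <- function(model) {
  structure(list(config = model$config,
                 params = list2env(as.list(model$params),
                                   parent = emptyenv()),
                 buffers = list2env(as.list(model$buffers),
                                    parent = emptyenv())),
            class = "kp_model")
}

#' @export
print.kp_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<hourglass model> %s, %d tasks, F=%d, depth=%d, input=%d, %s params\n",
              cfg$topology, length(cfg$tasks), cfg$n_features, cfg$depth,
              cfg$input_size, format(n_parameters(x), big.mark = ",")))
  invisible(x)
}
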