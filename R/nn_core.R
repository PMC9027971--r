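# Minimal CNN engine backing the hourglass detector: convolution (Rcpp
# im2col + GEMM), batch normalization, ReLU, 2x2 max pooling and nearest
# upsampling, each with a hand-written backward pass. Tensors are R arrays
# (H, W, C, N). Parameters and gradients live in environments keyed by
# layer name ("<name>.w", "<name>.g", ...) so updates are in place.

nn_init_conv <- function(ps, name, kh, kw, cin, cout, gain = 2) {
  sd <- sqrt(gain / (kh * kw * cin))
  ps[[paste0(name, ".w")]] <- array(rnorm(kh * kw * cin * cout, 0, sd),
                                    c(kh, kw, cin, cout))
  ps[[paste0(name, ".b")]] <- numeric(cout)
  invisible(NULL)
}

nn_init_bn <- function(ps, bufs, name, c) {
  ps[[paste0(name, ".g")]] <- rep(1, c)
  ps[[paste0(name, ".be")]] <- rep(0, c)
  bufs[[paste0(name, ".rm")]] <- rep(0, c)
  bufs[[paste0(name, ".rv")]] <- rep(1, c)
  invisible(NULL)
}

conv_f <- function(ps, name, x) {
  y <- cpp_conv2d_fwd(x, ps[[paste0(name, ".w")]], ps[[paste0(name, ".b")]])
  list(y = y, cache = list(x = x, name = name))
}

conv_b <- function(ps, gr, cache, dy) {
  name <- cache$name
  g <- cpp_conv2d_bwd(cache$x, ps[[paste0(name, ".w")]], dy)
  acc_grad(gr, paste0(name, ".w"), g$dw)
  acc_grad(gr, paste0(name, ".b"), g$db)
  g$dx
}

acc_grad <- function(gr, key, val) {
  if (is.null(gr[[key]])) gr[[key]] <- val else gr[[key]] <- gr[[key]] + val
}

channel_stats <- function(x, C) {
  HW <- dim(x)[1] * dim(x)[2]; N <- dim(x)[4]
  m <- matrix(x, HW, C * N)
  cm <- matrix(.colMeans(m, HW, C * N), C, N)
  rowMeans(cm)
}

bn_f <- function(ps, bufs, name, x, training, momentum = 0.1, eps = 1e-5) {
  g <- ps[[paste0(name, ".g")]]; be <- ps[[paste0(name, ".be")]]
  if (training) {
    mo <- cpp_channel_moments(x)
    mu <- mo$mean; v <- mo$var
    bufs[[paste0(name, ".rm")]] <-
      (1 - momentum) * bufs[[paste0(name, ".rm")]] + momentum * mu
    bufs[[paste0(name, ".rv")]] <-
      (1 - momentum) * bufs[[paste0(name, ".rv")]] + momentum * v
  } else {
    mu <- bufs[[paste0(name, ".rm")]]
    v <- bufs[[paste0(name, ".rv")]]
  }
  istd <- 1 / sqrt(v + eps)
  r <- cpp_bn_fwd(x, g, be, mu, istd)
  list(y = r$y, cache = list(xhat = r$xhat, istd = istd, name = name,
                             training = training))
}

bn_b <- function(ps, gr, cache, dy) {
  g <- ps[[paste0(cache$name, ".g")]]
  if (!cache$training) {
    HW <- dim(dy)[1] * dim(dy)[2]
    mo <- cpp_channel_moments(dy * cache$xhat)
    n_tot <- HW * dim(dy)[4]
    acc_grad(gr, paste0(cache$name, ".g"), mo$mean * n_tot)
    acc_grad(gr, paste0(cache$name, ".be"),
             cpp_channel_moments(dy)$mean * n_tot)
    return(dy * rep(g * cache$istd, each = HW))
  }
  r <- cpp_bn_bwd(dy, cache$xhat, g, cache$istd)
  acc_grad(gr, paste0(cache$name, ".g"), r$dg)
  acc_grad(gr, paste0(cache$name, ".be"), r$dbe)
  r$dx
}

relu_f <- function(x) {
  mask <- x > 0
  list(y = x * mask, cache = mask)
}

relu_b <- function(cache, dy) dy * cache

pool_f <- function(x) {
  r <- cpp_maxpool2_fwd(x)
  list(y = r$y, cache = list(idx = r$idx, xdim = dim(x)))
}

pool_b <- function(cache, dy) {
  cpp_maxpool2_bwd(dy, cache$idx, cache$xdim)
}

upsample_f <- function(x) {
  d <- dim(x)
  y <- x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
         drop = FALSE]
  list(y = y, cache = d)
}

upsample_b <- function(cache, dy) {
  h <- cache[1]; w <- cache[2]
  i1 <- seq(1, 2 * h, 2); i2 <- i1 + 1
  j1 <- seq(1, 2 * w, 2); j2 <- j1 + 1
  dy[i1, j1, , , drop = FALSE] + dy[i1, j2, , , drop = FALSE] +
    dy[i2, j1, , , drop = FALSE] + dy[i2, j2, , , drop = FALSE]
}

# Residual pre-activation bottleneck: BN-ReLU-1x1 (F -> F/2),
# BN-ReLU-3x3, BN-ReLU-1x1 (F/2 -> F), plus identity shortcut.
bottleneck_init <- function(ps, bufs, name, F) {
  mid <- max(1L, F %/% 2L)
  nn_init_bn(ps, bufs, paste0(name, ".bn1"), F)
  nn_init_conv(ps, paste0(name, ".c1"), 1, 1, F, mid)
  nn_init_bn(ps, bufs, paste0(name, ".bn2"), mid)
  nn_init_conv(ps, paste0(name, ".c2"), 3, 3, mid, mid)
  nn_init_bn(ps, bufs, paste0(name, ".bn3"), mid)
  nn_init_conv(ps, paste0(name, ".c3"), 1, 1, mid, F)
}

bottleneck_f <- function(ps, bufs, name, x, training) {
  b1 <- bn_f(ps, bufs, paste0(name, ".bn1"), x, training)
  r1 <- relu_f(b1$y)
  c1 <- conv_f(ps, paste0(name, ".c1"), r1$y)
  b2 <- bn_f(ps, bufs, paste0(name, ".bn2"), c1$y, training)
  r2 <- relu_f(b2$y)
  c2 <- conv_f(ps, paste0(name, ".c2"), r2$y)
  b3 <- bn_f(ps, bufs, paste0(name, ".bn3"), c2$y, training)
  r3 <- relu_f(b3$y)
  c3 <- conv_f(ps, paste0(name, ".c3"), r3$y)
  list(y = x + c3$y,
       cache = list(b1 = b1$cache, r1 = r1$cache, c1 = c1$cache,
                    b2 = b2$cache, r2 = r2$cache, c2 = c2$cache,
                    b3 = b3$cache, r3 = r3$cache, c3 = c3$cache))
}

bottleneck_b <- function(ps, gr, cache, dy) {
  d <- conv_b(ps, gr, cache$c3, dy)
  d <- relu_b(cache$r3, d)
  d <- bn_b(ps, gr, cache$b3, d)
  d <- conv_b(ps, gr, cache$c2, d)
  d <- relu_b(cache$r2, d)
  d <- bn_b(ps, gr, cache$b2, d)
  d <- conv_b(ps, gr, cache$c1, d)
  d <- relu_b(cache$r1, d)
  d <- bn_b(ps, gr, cache$b1, d)
  dy + d
}
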