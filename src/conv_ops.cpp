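// Numeric hot paths for the hourglass network and raster warping.
// Layout convention follows R arrays: image tensors are (H, W, C, N),
// column-major, y (row) index fastest; pixel centers sit at integer
// coordinates, origin at the center of the top-left pixel.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline NumericVector make4d(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline arma::mat im2col_same(const double* x, int H, int W, int Cin,
                                    int kh, int kw) {
  // rows: output pixel p = i + H*j; cols: r = ky + kh*(kx + kw*c)
  const int pad_y = (kh - 1) / 2, pad_x = (kw - 1) / 2;
  arma::mat X(H * W, kh * kw * Cin, arma::fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kx = 0; kx < kw; ++kx) {
      for (int ky = 0; ky < kh; ++ky) {
        const int col = ky + kh * (kx + kw * c);
        const int dy = ky - pad_y, dx = kx - pad_x;
        double* Xcol = X.colptr(col);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dx;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, -dy), i1 = std::min(H, H - dy);
          const double* src = xc + (size_t)sj * H + dy;
          double* dst = Xcol + (size_t)j * H;
          for (int i = i0; i < i1; ++i) dst[i] = src[i];
        }
      }
    }
  }
  return X;
}

static inline void col2im_same_add(const arma::mat& dX, double* dx, int H,
                                   int W, int Cin, int kh, int kw) {
  const int pad_y = (kh - 1) / 2, pad_x = (kw - 1) / 2;
  for (int c = 0; c < Cin; ++c) {
    double* xc = dx + (size_t)c * H * W;
    for (int kx = 0; kx < kw; ++kx) {
      for (int ky = 0; ky < kh; ++ky) {
        const int col = ky + kh * (kx + kw * c);
        const int dy = ky - pad_y, dx_ = kx - pad_x;
        const double* Xcol = dX.colptr(col);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dx_;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, -dy), i1 = std::min(H, H - dy);
          double* dst = xc + (size_t)sj * H + dy;
          const double* src = Xcol + (size_t)j * H;
          for (int i = i0; i < i1; ++i) dst[i] += src[i];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != Cin) stop("conv2d: channel mismatch");
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false);
  NumericVector y = make4d(H, W, Cout, N);
  for (int n = 0; n < N; ++n) {
    arma::mat X = im2col_same(x.begin() + (size_t)n * H * W * Cin, H, W, Cin,
                              kh, kw);
    arma::mat Y(y.begin() + (size_t)n * H * W * Cout, H * W, Cout, false,
                true);
    Y = X * Wm;
    for (int o = 0; o < Cout; ++o) Y.col(o) += b[o];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false);
  NumericVector dx = make4d(H, W, Cin, N);
  NumericVector dw = make4d(kh, kw, Cin, Cout);
  NumericVector db(Cout);
  arma::mat dWm(dw.begin(), kh * kw * Cin, Cout, false, true);
  for (int n = 0; n < N; ++n) {
    arma::mat X = im2col_same(x.begin() + (size_t)n * H * W * Cin, H, W, Cin,
                              kh, kw);
    arma::mat dY(const_cast<double*>(dy.begin()) + (size_t)n * H * W * Cout,
                 H * W, Cout, false);
    dWm += X.t() * dY;
    arma::mat dX = dY * Wm.t();
    col2im_same_add(dX, dx.begin() + (size_t)n * H * W * Cin, H, W, Cin, kh,
                    kw);
    for (int o = 0; o < Cout; ++o) db[o] += arma::accu(dY.col(o));
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Weight gradient only (used per task by GradNorm at the last shared layer).
// [[Rcpp::export]]
NumericVector cpp_conv2d_wgrad(NumericVector x, NumericVector dy,
                               IntegerVector ksize) {
  IntegerVector xd = x.attr("dim"), yd = dy.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = ksize[0], kw = ksize[1], Cout = yd[2];
  NumericVector dw = make4d(kh, kw, Cin, Cout);
  arma::mat dWm(dw.begin(), kh * kw * Cin, Cout, false, true);
  for (int n = 0; n < N; ++n) {
    arma::mat X = im2col_same(x.begin() + (size_t)n * H * W * Cin, H, W, Cin,
                              kh, kw);
    arma::mat dY(const_cast<double*>(dy.begin()) + (size_t)n * H * W * Cout,
                 H * W, Cout, false);
    dWm += X.t() * dY;
  }
  return dw;
}

// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = make4d(Ho, Wo, C, N);
  IntegerVector idx(Ho * Wo * C * N);  // 0-based index into x
  size_t q = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          size_t p00 = base + (size_t)(2 * j) * H + 2 * i;
          size_t cand[4] = {p00, p00 + 1, p00 + H, p00 + H + 1};
          size_t best = cand[0];
          double bv = x[best];
          for (int k = 1; k < 4; ++k)
            if (x[cand[k]] > bv) { bv = x[cand[k]]; best = cand[k]; }
          y[q] = bv;
          idx[q] = (int)best;
          ++q;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector dy, IntegerVector idx,
                               IntegerVector xdim) {
  NumericVector dx = make4d(xdim[0], xdim[1], xdim[2], xdim[3]);
  const R_xlen_t n = dy.size();
  for (R_xlen_t k = 0; k < n; ++k) dx[idx[k]] += dy[k];
  return dx;
}

static inline double keys_w(double t) {
  // Keys cubic convolution kernel, a = -0.5 (Catmull-Rom)
  t = std::fabs(t);
  if (t <= 1.0) return (1.5 * t - 2.5) * t * t + 1.0;
  if (t < 2.0) return ((-0.5 * t + 2.5) * t - 4.0) * t + 2.0;
  return 0.0;
}

// M maps output pixel-center coordinates (x, y) to source coordinates:
// sx = M[0]*x + M[1]*y + M[2]; sy = M[3]*x + M[4]*y + M[5].
// Outside-the-source samples contribute zero (zero padding).
// [[Rcpp::export]]
NumericMatrix cpp_warp_affine_bicubic(NumericMatrix img, NumericVector M,
                                      int out_h, int out_w) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(out_h, out_w);
  for (int x = 0; x < out_w; ++x) {
    for (int y = 0; y < out_h; ++y) {
      const double sx = M[0] * x + M[1] * y + M[2];
      const double sy = M[3] * x + M[4] * y + M[5];
      if (sx < -2 || sx > W + 1 || sy < -2 || sy > H + 1) continue;
      const int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
      double acc = 0.0;
      for (int jj = -1; jj <= 2; ++jj) {
        const int xs = x0 + jj;
        if (xs < 0 || xs >= W) continue;
        const double wx = keys_w(sx - xs);
        if (wx == 0.0) continue;
        for (int ii = -1; ii <= 2; ++ii) {
          const int ys = y0 + ii;
          if (ys < 0 || ys >= H) continue;
          const double wy = keys_w(sy - ys);
          if (wy != 0.0) acc += wx * wy * img(ys, xs);
        }
      }
      out(y, x) = acc;
    }
  }
  return out;
}

// Truncated Gaussian line heatmap: distance of each pixel center to the
// nearest point on the polyline (segment metric, round caps).
// pts is an n x 2 matrix of (x, y) vertices.
// [[Rcpp::export]]
NumericMatrix cpp_line_heatmap(NumericMatrix pts, int H, int W, double sigma) {
  const int n = pts.nrow();
  NumericMatrix out(H, W);
  const double r = 3.0 * sigma, inv2s2 = 1.0 / (2.0 * sigma * sigma);
  for (int s = 0; s + 1 < n; ++s) {
    const double ax = pts(s, 0), ay = pts(s, 1);
    const double bx = pts(s + 1, 0), by = pts(s + 1, 1);
    const double dx = bx - ax, dy = by - ay;
    const double len2 = dx * dx + dy * dy;
    const int xlo = std::max(0, (int)std::floor(std::min(ax, bx) - r));
    const int xhi = std::min(W - 1, (int)std::ceil(std::max(ax, bx) + r));
    const int ylo = std::max(0, (int)std::floor(std::min(ay, by) - r));
    const int yhi = std::min(H - 1, (int)std::ceil(std::max(ay, by) + r));
    for (int x = xlo; x <= xhi; ++x)
      for (int y = ylo; y <= yhi; ++y) {
        double t = len2 > 0 ? ((x - ax) * dx + (y - ay) * dy) / len2 : 0.0;
        t = std::min(1.0, std::max(0.0, t));
        const double px = ax + t * dx, py = ay + t * dy;
        const double d2 = (x - px) * (x - px) + (y - py) * (y - py);
        if (d2 <= r * r) {
          const double v = std::exp(-d2 * inv2s2);
          if (v > out(y, x)) out(y, x) = v;
        }
      }
  }
  return out;
}

// Symmetric average surface distance between two dense point sets (n x 2).
// [[Rcpp::export]]
double cpp_assd(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow();
  double total = 0.0;
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      const double dx = A(i, 0) - B(j, 0), dy = A(i, 1) - B(j, 1);
      const double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    total += std::sqrt(best);
  }
  for (int j = 0; j < nb; ++j) {
    double best = R_PosInf;
    for (int i = 0; i < na; ++i) {
      const double dx = A(i, 0) - B(j, 0), dy = A(i, 1) - B(j, 1);
      const double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    total += std::sqrt(best);
  }
  return total / (na + nb);
}

// Per-channel mean and (biased) variance over (H, W, N) of an (H,W,C,N)
// tensor.
// [[Rcpp::export]]
List cpp_channel_moments(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const size_t HW = (size_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  NumericVector mu(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    const double m = s / (HW * N);
    mu[c] = m;
    var[c] = s2 / (HW * N) - m * m;
  }
  return List::create(_["mean"] = mu, _["var"] = var);
}

// y = gamma * (x - mu) * istd + beta; also returns xhat for the backward.
// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, NumericVector g, NumericVector be,
                NumericVector mu, NumericVector istd) {
  IntegerVector xd = x.attr("dim");
  const size_t HW = (size_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  NumericVector y = make4d(xd[0], xd[1], xd[2], xd[3]);
  NumericVector xh = make4d(xd[0], xd[1], xd[2], xd[3]);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)n * C + c) * HW;
      const double m = mu[c], is = istd[c], gc = g[c], bc = be[c];
      const double* px = x.begin() + off;
      double* py = y.begin() + off;
      double* ph = xh.begin() + off;
      for (size_t i = 0; i < HW; ++i) {
        const double h = (px[i] - m) * is;
        ph[i] = h;
        py[i] = gc * h + bc;
      }
    }
  return List::create(_["y"] = y, _["xhat"] = xh);
}

// Training-mode batchnorm backward.
// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector dy, NumericVector xhat, NumericVector g,
                NumericVector istd) {
  IntegerVector xd = dy.attr("dim");
  const size_t HW = (size_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  const double m = (double)HW * N;
  NumericVector dx = make4d(xd[0], xd[1], xd[2], xd[3]);
  NumericVector dg(C), dbe(C);
  std::vector<double> s1(C, 0.0), s2(C, 0.0);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)n * C + c) * HW;
      const double* pd = dy.begin() + off;
      const double* ph = xhat.begin() + off;
      double a = 0.0, b2 = 0.0;
      for (size_t i = 0; i < HW; ++i) { a += pd[i]; b2 += pd[i] * ph[i]; }
      dbe[c] += a;
      dg[c] += b2;
      s1[c] += a * g[c];
      s2[c] += b2 * g[c];
    }
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)n * C + c) * HW;
      const double* pd = dy.begin() + off;
      const double* ph = xhat.begin() + off;
      double* px = dx.begin() + off;
      const double gc = g[c], is = istd[c];
      const double t1 = s1[c] / m, t2 = s2[c] / m;
      for (size_t i = 0; i < HW; ++i) {
        px[i] = (gc * pd[i] - t1 - ph[i] * t2) * is;
      }
    }
  return List::create(_["dx"] = dx, _["dg"] = dg, _["dbe"] = dbe);
}
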