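// Low-level numeric kernels: conv/pool/upconv/batch-norm layers (im2col + GEMM),
// image resampling, grayscale morphology, Gaussian smoothing, component labeling.
// Array layout convention matches R: column-major, activations [H, W, C, N],
// conv weights [KH, KW, C_in, C_out], transposed-conv weights [2, 2, C_out, C_in].
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * (R_xlen_t)c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector alloc4i(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * (R_xlen_t)c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline arma::uvec dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array");
  return arma::uvec{(unsigned)d[0], (unsigned)d[1], (unsigned)d[2], (unsigned)d[3]};
}

// gather one image into rows [row0, row0+H*W) of a column-strided (ld rows)
// im2col matrix: cols indexed (ki, kj, c); same padding, zero fill.
// Convolution arithmetic runs in single precision (standard for CNN training;
// halves memory traffic and doubles GEMM throughput on this BLAS).
static void im2col_strided(const double* x, int H, int W, int C, int KH, int KW,
                           float* dest, size_t row0, size_t ld) {
  const int ph = (KH - 1) / 2, pw = (KW - 1) / 2;
  const int HW = H * W;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * HW;
    for (int kj = 0; kj < KW; ++kj) {
      for (int ki = 0; ki < KH; ++ki) {
        float* dst = dest + (size_t)(ki + KH * (kj + KW * c)) * ld + row0;
        const int di = ki - ph, dj = kj - pw;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj;
          float* d = dst + (size_t)j * H;
          if (sj < 0 || sj >= W) { std::fill(d, d + H, 0.0f); continue; }
          const double* s = xc + (size_t)sj * H;
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          for (int i = 0; i < i0; ++i) d[i] = 0.0f;
          for (int i = i0; i < i1; ++i) d[i] = (float)s[i + di];
          for (int i = i1; i < H; ++i) d[i] = 0.0f;
        }
      }
    }
  }
}

// scatter-add rows [row0, row0+H*W) of a strided im2col gradient back to dx
static void col2im_add_strided(const float* col, int H, int W, int C,
                               int KH, int KW, double* x,
                               size_t row0, size_t ld) {
  const int ph = (KH - 1) / 2, pw = (KW - 1) / 2;
  const int HW = H * W;
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)c * HW;
    for (int kj = 0; kj < KW; ++kj) {
      for (int ki = 0; ki < KH; ++ki) {
        const float* src = col + (size_t)(ki + KH * (kj + KW * c)) * ld + row0;
        const int di = ki - ph, dj = kj - pw;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          const float* s = src + (size_t)j * H;
          double* d = xc + (size_t)sj * H;
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          for (int i = i0; i < i1; ++i) d[i + di] += s[i];
        }
      }
    }
  }
}

static arma::fmat to_fmat(const double* p, size_t n, size_t m) {
  arma::fmat out(n, m);
  float* o = out.memptr();
  for (size_t i = 0; i < n * m; ++i) o[i] = (float)p[i];
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  arma::uvec dx = dims4(x), dw = dims4(w);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int KH = dw[0], KW = dw[1], F = dw[3];
  if ((int)dw[2] != C) stop("conv: channel mismatch");
  const int HW = H * W, K = KH * KW * C;
  arma::fmat Wm = to_fmat(w.begin(), K, F);
  NumericVector y = alloc4(H, W, F, N);
  arma::fmat col(HW, K); // per-image blocking keeps the working set in cache
  for (int n = 0; n < N; ++n) {
    im2col_strided(x.begin() + (size_t)n * HW * C, H, W, C, KH, KW,
                   col.memptr(), 0, HW);
    arma::fmat out = col * Wm; // HW x F
    for (int f = 0; f < F; ++f) {
      const float* s = out.colptr(f);
      double* d = y.begin() + (size_t)n * HW * F + (size_t)f * HW;
      const double bias = b[f];
      for (int i = 0; i < HW; ++i) d[i] = (double)s[i] + bias;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  arma::uvec dxd = dims4(x), dwd = dims4(w);
  const int H = dxd[0], W = dxd[1], C = dxd[2], N = dxd[3];
  const int KH = dwd[0], KW = dwd[1], F = dwd[3];
  const int HW = H * W, K = KH * KW * C;
  arma::fmat Wm = to_fmat(w.begin(), K, F);
  NumericVector dxv = alloc4(H, W, C, N);
  NumericVector dwv = alloc4(KH, KW, C, F);
  NumericVector dbv(F);
  arma::fmat dW(K, F, arma::fill::zeros);
  arma::fvec dB(F, arma::fill::zeros);
  arma::fmat col(HW, K), dY(HW, F);
  for (int n = 0; n < N; ++n) {
    im2col_strided(x.begin() + (size_t)n * HW * C, H, W, C, KH, KW,
                   col.memptr(), 0, HW);
    for (int f = 0; f < F; ++f) {
      const double* s = dy.begin() + (size_t)n * HW * F + (size_t)f * HW;
      float* d = dY.colptr(f);
      for (int i = 0; i < HW; ++i) d[i] = (float)s[i];
    }
    dW += col.t() * dY;
    dB += arma::sum(dY, 0).t();
    arma::fmat dcol = dY * Wm.t(); // HW x K
    col2im_add_strided(dcol.memptr(), H, W, C, KH, KW,
                       dxv.begin() + (size_t)n * HW * C, 0, HW);
  }
  std::copy(dW.begin(), dW.end(), dwv.begin());
  for (int f = 0; f < F; ++f) dbv[f] = dB[f];
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  arma::uvec d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("maxpool: odd spatial dims");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = alloc4(Ho, Wo, C, N);
  IntegerVector idx = alloc4i(Ho, Wo, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  const size_t plane = (size_t)H * W;
  for (long cn = 0; cn < (long)C * N; ++cn) {
    const double* xs = xp + plane * cn;
    double* ys = yp + (size_t)Ho * Wo * cn;
    int* is = ip + (size_t)Ho * Wo * cn;
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        int base = 2 * i + H * 2 * j;
        int off[4] = {0, 1, H, H + 1};
        int best = 0; double bv = xs[base];
        for (int k = 1; k < 4; ++k)
          if (xs[base + off[k]] > bv) { bv = xs[base + off[k]]; best = k; }
        ys[i + Ho * j] = bv;
        is[i + Ho * j] = best;
      }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector dy, IntegerVector idx, int H, int W) {
  arma::uvec d = dims4(dy);
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  NumericVector dx = alloc4(H, W, C, N);
  const double* dp = dy.begin();
  const int* ip = idx.begin();
  double* xp = dx.begin();
  const size_t plane = (size_t)H * W;
  for (long cn = 0; cn < (long)C * N; ++cn) {
    double* xs = xp + plane * cn;
    const double* ds = dp + (size_t)Ho * Wo * cn;
    const int* is = ip + (size_t)Ho * Wo * cn;
    int off[4] = {0, 1, H, H + 1};
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        int base = 2 * i + H * 2 * j;
        xs[base + off[is[i + Ho * j]]] += ds[i + Ho * j];
      }
  }
  return dx;
}

// transposed conv, kernel 2x2, stride 2 (non-overlapping): w is [2,2,F,C]
// [[Rcpp::export]]
NumericVector cpp_upconv2_fwd(NumericVector x, NumericVector w, NumericVector b) {
  arma::uvec dx = dims4(x), dw = dims4(w);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int F = dw[2];
  if ((int)dw[3] != C) stop("upconv: channel mismatch");
  const int HW = H * W;
  arma::mat Wm(const_cast<double*>(w.begin()), 4 * F, C, false, true);
  NumericVector y = alloc4(2 * H, 2 * W, F, N);
  for (int n = 0; n < N; ++n) {
    arma::mat Xm(const_cast<double*>(x.begin()) + (size_t)n * HW * C, HW, C, false, true);
    arma::mat Y = Xm * Wm.t(); // HW x 4F
    double* yn = y.begin() + (size_t)n * 4 * HW * F;
    for (int f = 0; f < F; ++f) {
      const size_t yoff = (size_t)f * 4 * HW;
      for (int kj = 0; kj < 2; ++kj)
        for (int ki = 0; ki < 2; ++ki) {
          const double* s = Y.colptr(ki + 2 * kj + 4 * f);
          const double bias = b[f];
          for (int j = 0; j < W; ++j) {
            double* d = yn + yoff + (size_t)(2 * j + kj) * 2 * H + ki;
            const double* ss = s + (size_t)j * H;
            for (int i = 0; i < H; ++i) d[2 * i] = ss[i] + bias;
          }
        }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_upconv2_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  arma::uvec dxd = dims4(x), dwd = dims4(w);
  const int H = dxd[0], W = dxd[1], C = dxd[2], N = dxd[3];
  const int F = dwd[2];
  const int HW = H * W;
  arma::mat Wm(const_cast<double*>(w.begin()), 4 * F, C, false, true);
  NumericVector dxv = alloc4(H, W, C, N);
  NumericVector dwv = alloc4(2, 2, F, C);
  NumericVector dbv(F);
  arma::mat dW(dwv.begin(), 4 * F, C, false, true);
  arma::mat dYm(HW, 4 * F);
  for (int n = 0; n < N; ++n) {
    const double* yn = dy.begin() + (size_t)n * 4 * HW * F;
    for (int f = 0; f < F; ++f) {
      const size_t yoff = (size_t)f * 4 * HW;
      for (int kj = 0; kj < 2; ++kj)
        for (int ki = 0; ki < 2; ++ki) {
          double* d = dYm.colptr(ki + 2 * kj + 4 * f);
          for (int j = 0; j < W; ++j) {
            const double* s = yn + yoff + (size_t)(2 * j + kj) * 2 * H + ki;
            double* dd = d + (size_t)j * H;
            for (int i = 0; i < H; ++i) dd[i] = s[2 * i];
          }
        }
      double acc = 0.0;
      for (int q = 0; q < 4; ++q) acc += arma::accu(dYm.col(q + 4 * f));
      dbv[f] += acc;
    }
    arma::mat Xm(const_cast<double*>(x.begin()) + (size_t)n * HW * C, HW, C, false, true);
    dW += dYm.t() * Xm;
    arma::mat dX = dYm * Wm; // HW x C
    std::copy(dX.begin(), dX.end(), dxv.begin() + (size_t)n * HW * C);
  }
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// batch norm over (H, W, N) per channel; biased variance
// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta, double eps) {
  arma::uvec d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t HW = (size_t)H * W;
  NumericVector y = alloc4(H, W, C, N);
  NumericVector mu(C), var(C);
  const double m = (double)HW * N;
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* xs = x.begin() + HW * (c + (size_t)n * C);
      for (size_t i = 0; i < HW; ++i) { s += xs[i]; s2 += xs[i] * xs[i]; }
    }
    const double mean = s / m;
    const double v = std::max(0.0, s2 / m - mean * mean);
    mu[c] = mean; var[c] = v;
    const double a = gamma[c] / std::sqrt(v + eps);
    const double b0 = beta[c] - a * mean;
    for (int n = 0; n < N; ++n) {
      const double* xs = x.begin() + HW * (c + (size_t)n * C);
      double* ys = y.begin() + HW * (c + (size_t)n * C);
      for (size_t i = 0; i < HW; ++i) ys[i] = a * xs[i] + b0;
    }
  }
  return List::create(_["y"] = y, _["mean"] = mu, _["var"] = var);
}

// [[Rcpp::export]]
NumericVector cpp_bn_infer(NumericVector x, NumericVector gamma, NumericVector beta,
                           NumericVector rmean, NumericVector rvar, double eps) {
  arma::uvec d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t HW = (size_t)H * W;
  NumericVector y = alloc4(H, W, C, N);
  for (int c = 0; c < C; ++c) {
    const double a = gamma[c] / std::sqrt(rvar[c] + eps);
    const double b0 = beta[c] - a * rmean[c];
    for (int n = 0; n < N; ++n) {
      const double* xs = x.begin() + HW * (c + (size_t)n * C);
      double* ys = y.begin() + HW * (c + (size_t)n * C);
      for (size_t i = 0; i < HW; ++i) ys[i] = a * xs[i] + b0;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector x, NumericVector dy, NumericVector gamma,
                NumericVector mu, NumericVector var, double eps) {
  arma::uvec d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t HW = (size_t)H * W;
  const double m = (double)HW * N;
  NumericVector dx = alloc4(H, W, C, N);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double istd = 1.0 / std::sqrt(var[c] + eps);
    double sdy = 0, sdyx = 0;
    for (int n = 0; n < N; ++n) {
      const double* xs = x.begin() + HW * (c + (size_t)n * C);
      const double* ds = dy.begin() + HW * (c + (size_t)n * C);
      for (size_t i = 0; i < HW; ++i) {
        sdy += ds[i];
        sdyx += ds[i] * (xs[i] - mu[c]) * istd;
      }
    }
    dgamma[c] = sdyx; dbeta[c] = sdy;
    const double k1 = gamma[c] * istd;
    const double mdy = sdy / m, mdyx = sdyx / m;
    for (int n = 0; n < N; ++n) {
      const double* xs = x.begin() + HW * (c + (size_t)n * C);
      const double* ds = dy.begin() + HW * (c + (size_t)n * C);
      double* dd = dx.begin() + HW * (c + (size_t)n * C);
      for (size_t i = 0; i < HW; ++i) {
        const double xhat = (xs[i] - mu[c]) * istd;
        dd[i] = k1 * (ds[i] - mdy - xhat * mdyx);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericVector cpp_relu_fwd(NumericVector x) {
  NumericVector y = clone(x);
  for (double& v : y) if (v < 0) v = 0;
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector dy, NumericVector y) {
  NumericVector dx = clone(dy);
  for (R_xlen_t i = 0; i < dx.size(); ++i) if (y[i] <= 0) dx[i] = 0;
  return dx;
}

// global average pooling: [H,W,C,N] -> C x N matrix
// [[Rcpp::export]]
NumericMatrix cpp_gap_fwd(NumericVector x) {
  arma::uvec d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t HW = (size_t)H * W;
  NumericMatrix y(C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + HW * (c + (size_t)n * C);
      double s = 0;
      for (size_t i = 0; i < HW; ++i) s += xs[i];
      y(c, n) = s / (double)HW;
    }
  return y;
}

// ---- resampling -------------------------------------------------------------

static inline double sample_bilinear(const NumericMatrix& img, double si, double sj) {
  const int H = img.nrow(), W = img.ncol();
  if (si < -0.5 || si > H - 0.5 || sj < -0.5 || sj > W - 0.5) return NA_REAL;
  si = std::min(std::max(si, 0.0), (double)(H - 1));
  sj = std::min(std::max(sj, 0.0), (double)(W - 1));
  const int i0 = (int)std::floor(si), j0 = (int)std::floor(sj);
  const int i1 = std::min(i0 + 1, H - 1), j1 = std::min(j0 + 1, W - 1);
  const double fi = si - i0, fj = sj - j0;
  return (1 - fi) * (1 - fj) * img(i0, j0) + fi * (1 - fj) * img(i1, j0) +
         (1 - fi) * fj * img(i0, j1) + fi * fj * img(i1, j1);
}

// [[Rcpp::export]]
NumericMatrix cpp_resize(NumericMatrix img, int oh, int ow, bool bilinear) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(oh, ow);
  const double si = (double)H / oh, sj = (double)W / ow;
  for (int j = 0; j < ow; ++j)
    for (int i = 0; i < oh; ++i) {
      const double yi = (i + 0.5) * si - 0.5, xj = (j + 0.5) * sj - 0.5;
      if (bilinear) {
        double y = std::min(std::max(yi, 0.0), (double)(H - 1));
        double x = std::min(std::max(xj, 0.0), (double)(W - 1));
        out(i, j) = sample_bilinear(img, y, x);
      } else {
        int ii = std::min(std::max((int)std::lround(yi), 0), H - 1);
        int jj = std::min(std::max((int)std::lround(xj), 0), W - 1);
        out(i, j) = img(ii, jj);
      }
    }
  return out;
}

// affine resample about the image center: inverse map is
// rotate(-angle) -> scale(1/s) -> flips; outside-source pixels take `fill`.
// [[Rcpp::export]]
NumericMatrix cpp_affine_resample(NumericMatrix img, double angle_deg, double scale,
                                  bool flip_x, bool flip_y, bool bilinear, double fill) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  const double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0;
  const double th = -angle_deg * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double vy = i - cy, vx = j - cx;
      double ry = st * vx + ct * vy, rx = ct * vx - st * vy;
      ry /= scale; rx /= scale;
      if (flip_x) rx = -rx;
      if (flip_y) ry = -ry;
      const double si = ry + cy, sj = rx + cx;
      double v;
      if (bilinear) {
        v = sample_bilinear(img, si, sj);
        if (ISNA(v)) v = fill;
      } else {
        int ii = (int)std::lround(si), jj = (int)std::lround(sj);
        v = (ii < 0 || ii >= H || jj < 0 || jj >= W) ? fill : img(ii, jj);
      }
      out(i, j) = v;
    }
  return out;
}

// ---- morphology, smoothing, labeling ---------------------------------------

// grayscale erosion/dilation with a disk; out-of-image samples are ignored
// [[Rcpp::export]]
NumericMatrix cpp_morph_disk(NumericMatrix img, int radius, bool dilate) {
  const int H = img.nrow(), W = img.ncol();
  std::vector<std::pair<int,int>> se;
  for (int dj = -radius; dj <= radius; ++dj)
    for (int di = -radius; di <= radius; ++di)
      if (di * di + dj * dj <= radius * radius) se.push_back({di, dj});
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double best = dilate ? -INFINITY : INFINITY;
      for (auto& o : se) {
        const int ii = i + o.first, jj = j + o.second;
        if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
        const double v = img(ii, jj);
        best = dilate ? std::max(best, v) : std::min(best, v);
      }
      out(i, j) = best;
    }
  return out;
}

// separable Gaussian blur, reflect padding
// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(NumericMatrix img, double sigma) {
  const int H = img.nrow(), W = img.ncol();
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma)); s += k[i + r]; }
  for (auto& v : k) v /= s;
  auto reflect = [](int i, int n) {
    while (i < 0 || i >= n) { if (i < 0) i = -i - 1; if (i >= n) i = 2 * n - i - 1; }
    return i;
  };
  NumericMatrix tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double acc = 0;
      for (int q = -r; q <= r; ++q) acc += k[q + r] * img(reflect(i + q, H), j);
      tmp(i, j) = acc;
    }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double acc = 0;
      for (int q = -r; q <= r; ++q) acc += k[q + r] * tmp(i, reflect(j + q, W));
      out(i, j) = acc;
    }
  return out;
}

// 8-connected component labeling of a binary matrix
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(i + H * j);
      lab(i, j) = next;
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int pi = p % H, pj = p / H;
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            const int ii = pi + di, jj = pj + dj;
            if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
            if (mask(ii, jj) != 0 && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              stack.push_back(ii + H * jj);
            }
          }
      }
    }
  return lab;
}
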