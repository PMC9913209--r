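// Minimal batched 2-D convolution kernels for the transfer-learning backbone.
// Layout conventions match R column-major arrays:
//   images  : H x W x C x N
//   weights : (k*k*Cin) x Cout, rows ordered ki (fastest), kj, c
// im2col rows are ordered ho (fastest), wo, so a Ho*Wo x Cout product maps
// directly onto an Ho x Wo x Cout slice.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col(const double* xn, int H, int W, int C,
                   int k, int stride, int pad, int Ho, int Wo,
                   arma::mat& xcol) {
  xcol.zeros();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        int col = ki + k * (kj + k * c);
        double* dst = xcol.colptr(col);
        for (int wo = 0; wo < Wo; ++wo) {
          int ws = wo * stride - pad + kj;
          if (ws < 0 || ws >= W) continue;
          const double* xc = xn + (size_t)H * (ws + (size_t)W * c);
          for (int ho = 0; ho < Ho; ++ho) {
            int hs = ho * stride - pad + ki;
            if (hs < 0 || hs >= H) continue;
            dst[ho + Ho * wo] = xc[hs];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cppConvForward(NumericVector x, NumericMatrix w, NumericVector b,
                             int k, int stride, int pad) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  int Cout = w.ncol();
  if (w.nrow() != k * k * C) stop("weight rows do not match k*k*Cin");
  arma::mat Wm(w.begin(), w.nrow(), Cout, false);
  arma::rowvec bv(b.begin(), Cout);
  NumericVector y((R_xlen_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat xcol(Ho * Wo, k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, stride, pad, Ho, Wo, xcol);
    arma::mat ym(y.begin() + (size_t)Ho * Wo * Cout * n, Ho * Wo, Cout, false, true);
    ym = xcol * Wm;
    ym.each_row() += bv;
  }
  return y;
}

// Backward pass: given upstream gradient dy (Ho x Wo x Cout x N), returns
// gradients wrt input, weights and bias. im2col is recomputed (cheaper than
// caching it across the batch).
// [[Rcpp::export]]
List cppConvBackward(NumericVector x, NumericVector dy, NumericMatrix w,
                     int k, int stride, int pad) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  IntegerVector dd = dy.attr("dim");
  int Ho = dd[0], Wo = dd[1], Cout = dd[2];
  arma::mat Wm(w.begin(), w.nrow(), Cout, false);
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = d;
  arma::mat dW(w.nrow(), Cout, arma::fill::zeros);
  arma::rowvec db(Cout, arma::fill::zeros);
  arma::mat xcol(Ho * Wo, k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, stride, pad, Ho, Wo, xcol);
    arma::mat dym((double*)dy.begin() + (size_t)Ho * Wo * Cout * n, Ho * Wo, Cout, false);
    dW += xcol.t() * dym;
    db += arma::sum(dym, 0);
    arma::mat dxcol = dym * Wm.t();
    double* dxn = dx.begin() + (size_t)H * W * C * n;
    for (int c = 0; c < C; ++c) {
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          int col = ki + k * (kj + k * c);
          const double* src = dxcol.colptr(col);
          for (int wo = 0; wo < Wo; ++wo) {
            int ws = wo * stride - pad + kj;
            if (ws < 0 || ws >= W) continue;
            double* xc = dxn + (size_t)H * (ws + (size_t)W * c);
            for (int ho = 0; ho < Ho; ++ho) {
              int hs = ho * stride - pad + ki;
              if (hs < 0 || hs >= H) continue;
              xc[hs] += src[ho + Ho * wo];
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx,
                      _["dW"] = NumericMatrix(w.nrow(), Cout, dW.memptr()),
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Non-overlapping f x f average pooling over the two leading dims.
// [[Rcpp::export]]
NumericVector cppAvgPool(NumericVector x, int f) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % f || W % f) stop("spatial size not divisible by pool factor");
  int Ho = H / f, Wo = W / f;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  double inv = 1.0 / (f * f);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* xs = xp + (size_t)H * W * cn;
    double* ys = yp + (size_t)Ho * Wo * cn;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double s = 0.0;
        for (int dw = 0; dw < f; ++dw) {
          const double* colp = xs + (size_t)H * (wo * f + dw) + ho * f;
          for (int dh = 0; dh < f; ++dh) s += colp[dh];
        }
        ys[ho + Ho * wo] = s * inv;
      }
    }
  }
  return y;
}

// Fused Adam update for one tensor; returns updated (p, m, v) in one pass.
// [[Rcpp::export]]
List cppAdamUpdate(NumericVector p, NumericVector g, NumericVector m,
                   NumericVector v, double lr, double b1, double b2,
                   double eps, int t) {
  R_xlen_t n = p.size();
  NumericVector p2(n), m2(n), v2(n);
  double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
  for (R_xlen_t i = 0; i < n; ++i) {
    double mi = b1 * m[i] + (1.0 - b1) * g[i];
    double vi = b2 * v[i] + (1.0 - b2) * g[i] * g[i];
    m2[i] = mi; v2[i] = vi;
    p2[i] = p[i] - lr * (mi / c1) / (std::sqrt(vi / c2) + eps);
  }
  p2.attr("dim") = p.attr("dim");
  return List::create(_["p"] = p2, _["m"] = m2, _["v"] = v2);
}

// Pixel composition of the synthetic nodule renderer. All random inputs are
// drawn in R (so determinism lives with the R RNG); this routine is a pure
// function of its arguments.
// [[Rcpp::export]]
NumericMatrix cppRenderNodule(int size, double fovMm, double R0,
                              NumericVector lobFr, NumericVector lobPh,
                              NumericVector spikeAng, NumericVector spikeLen,
                              double roughAmp, NumericVector roughPh,
                              NumericMatrix texW, NumericVector texPh,
                              double texSd, double base, double background,
                              NumericVector noise, double edgeMm) {
  NumericMatrix img(size, size);
  double sc = size / fovMm;
  int L = lobFr.size(), S = spikeAng.size(), T = texPh.size();
  double lobNorm = L > 0 ? 0.12 / std::sqrt((double)L) : 0.0;
  double texAmp = texSd / std::sqrt(2.0);
  for (int j = 0; j < size; ++j) {
    double x = (j + 1 - (size + 1) / 2.0) / sc;
    for (int i = 0; i < size; ++i) {
      double y = (i + 1 - (size + 1) / 2.0) / sc;
      double r = std::sqrt(x * x + y * y);
      double th = std::atan2(y, x);
      double bnd = 1.0;
      for (int l = 0; l < L; ++l)
        bnd += lobNorm * std::sin(lobFr[l] * th + lobPh[l]);
      for (int s = 0; s < S; ++s) {
        double m = th - spikeAng[s] + M_PI;
        m -= 2 * M_PI * std::floor(m / (2 * M_PI));   // wrap to [0, 2pi)
        double d = std::fabs(m - M_PI);
        bnd += spikeLen[s] * std::exp(-(d / 0.07) * (d / 0.07));
      }
      if (roughAmp > 0)
        bnd += roughAmp * 0.1 * (std::sin(9 * th + roughPh[0]) +
                                 std::sin(14 * th + roughPh[1]));
      double tex = 0.0;
      for (int t = 0; t < T; ++t)
        tex += std::sin(texW(t, 0) * x + texW(t, 1) * y + texPh[t]);
      tex *= texAmp;
      double inside = 1.0 / (1.0 + std::exp(-(R0 * bnd - r) / edgeMm));
      double ext = background + 12.0 * noise[i + (size_t)size * j];
      img(i, j) = ext * (1.0 - inside) + (base + tex) * inside;
    }
  }
  return img;
}
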