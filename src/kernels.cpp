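// Hot inner kernels of the network engine. Batches are column-major arrays
// (n, L, C); im2col rows are ordered (i, t) and columns (j, c) so the R side
// can reshape with bare `dim<-` and feed BLAS directly.

#include <Rcpp.h>
using namespace Rcpp;

// (n, L, C) array -> (n*Lo) x (k*C) patch matrix for a valid convolution
// with stride s; each (t, j, c) block is a contiguous copy of n samples.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector X, int n, int L, int C, int k, int s) {
  int Lo = (L - k) / s + 1;
  NumericMatrix out(n * Lo, k * C);
  const double *x = X.begin();
  double *o = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < k; ++j) {
      double *ocol = o + ((R_xlen_t)(c * k + j)) * n * Lo;
      for (int t = 0; t < Lo; ++t) {
        const double *src = x + ((R_xlen_t)c * L + (R_xlen_t)(t * s + j)) * n;
        std::copy(src, src + n, ocol + (R_xlen_t)t * n);
      }
    }
  }
  return out;
}

// adjoint of cpp_im2col: scatter-add patch gradients back onto the input
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix dXc, int n, int L, int C, int k,
                         int s) {
  int Lo = (L - k) / s + 1;
  NumericVector dX((R_xlen_t)n * L * C);
  const double *g = dXc.begin();
  double *o = dX.begin();
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < k; ++j) {
      const double *gcol = g + ((R_xlen_t)(c * k + j)) * n * Lo;
      for (int t = 0; t < Lo; ++t) {
        double *dst = o + ((R_xlen_t)c * L + (R_xlen_t)(t * s + j)) * n;
        const double *src = gcol + (R_xlen_t)t * n;
        for (int i = 0; i < n; ++i) dst[i] += src[i];
      }
    }
  }
  dX.attr("dim") = IntegerVector::create(n, L, C);
  return dX;
}

// per-column mean and (population) variance in one pass
// [[Rcpp::export]]
List cpp_colstats(NumericMatrix X) {
  int m = X.nrow(), C = X.ncol();
  NumericVector mean(C), var(C);
  for (int c = 0; c < C; ++c) {
    const double *col = X.begin() + (R_xlen_t)c * m;
    double s = 0, s2 = 0;
    for (int i = 0; i < m; ++i) s += col[i];
    double mu = s / m;
    for (int i = 0; i < m; ++i) {
      double d = col[i] - mu;
      s2 += d * d;
    }
    mean[c] = mu;
    var[c] = s2 / m;
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// batch-norm transform: returns xhat = (x - mu) * invstd and
// y = gamma * xhat + beta, both m x C
// [[Rcpp::export]]
List cpp_bn_apply(NumericMatrix X, NumericVector mu, NumericVector invstd,
                  NumericVector gamma, NumericVector beta) {
  int m = X.nrow(), C = X.ncol();
  NumericMatrix xhat(m, C), y(m, C);
  for (int c = 0; c < C; ++c) {
    const double *col = X.begin() + (R_xlen_t)c * m;
    double *xh = xhat.begin() + (R_xlen_t)c * m;
    double *yy = y.begin() + (R_xlen_t)c * m;
    double mu_c = mu[c], is_c = invstd[c], g_c = gamma[c], b_c = beta[c];
    for (int i = 0; i < m; ++i) {
      double v = (col[i] - mu_c) * is_c;
      xh[i] = v;
      yy[i] = g_c * v + b_c;
    }
  }
  return List::create(_["xhat"] = xhat, _["y"] = y);
}

// batch-norm backward (batch statistics): given upstream dY and cached xhat,
// returns dX plus the gamma/beta gradients
// [[Rcpp::export]]
List cpp_bn_backward(NumericMatrix dY, NumericMatrix xhat,
                     NumericVector gamma, NumericVector invstd) {
  int m = dY.nrow(), C = dY.ncol();
  NumericMatrix dX(m, C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double *dy = dY.begin() + (R_xlen_t)c * m;
    const double *xh = xhat.begin() + (R_xlen_t)c * m;
    double *dx = dX.begin() + (R_xlen_t)c * m;
    double s_dy = 0, s_dyxh = 0;
    for (int i = 0; i < m; ++i) {
      s_dy += dy[i];
      s_dyxh += dy[i] * xh[i];
    }
    dgamma[c] = s_dyxh;
    dbeta[c] = s_dy;
    double g_is = gamma[c] * invstd[c];
    double mean_dy = s_dy / m, mean_dyxh = s_dyxh / m;
    for (int i = 0; i < m; ++i) {
      dx[i] = g_is * (dy[i] - mean_dy - xh[i] * mean_dyxh);
    }
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// non-overlapping max pool over the length dimension of an (n, L, C) array;
// ties keep the earliest position. amax holds the winning offset in 0..p-1.
// [[Rcpp::export]]
List cpp_maxpool(NumericVector X, int n, int L, int C, int p) {
  int Lo = L / p;
  NumericVector Y((R_xlen_t)n * Lo * C);
  IntegerVector amax((R_xlen_t)n * Lo * C);
  const double *x = X.begin();
  double *y = Y.begin();
  int *am = amax.begin();
  for (int c = 0; c < C; ++c) {
    for (int t = 0; t < Lo; ++t) {
      const double *base = x + ((R_xlen_t)c * L + (R_xlen_t)t * p) * n;
      double *yo = y + ((R_xlen_t)c * Lo + t) * n;
      int *ao = am + ((R_xlen_t)c * Lo + t) * n;
      for (int i = 0; i < n; ++i) {
        double best = base[i];
        int arg = 0;
        for (int r = 1; r < p; ++r) {
          double v = base[(R_xlen_t)r * n + i];
          if (v > best) { best = v; arg = r; }
        }
        yo[i] = best;
        ao[i] = arg;
      }
    }
  }
  Y.attr("dim") = IntegerVector::create(n, Lo, C);
  return List::create(_["Y"] = Y, _["amax"] = amax);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(NumericVector dY, IntegerVector amax,
                                   int n, int L, int C, int p) {
  int Lo = L / p;
  NumericVector dX((R_xlen_t)n * L * C);
  const double *dy = dY.begin();
  const int *am = amax.begin();
  double *dx = dX.begin();
  for (int c = 0; c < C; ++c) {
    for (int t = 0; t < Lo; ++t) {
      const double *dyo = dy + ((R_xlen_t)c * Lo + t) * n;
      const int *ao = am + ((R_xlen_t)c * Lo + t) * n;
      double *base = dx + ((R_xlen_t)c * L + (R_xlen_t)t * p) * n;
      for (int i = 0; i < n; ++i) {
        base[(R_xlen_t)ao[i] * n + i] += dyo[i];
      }
    }
  }
  dX.attr("dim") = IntegerVector::create(n, L, C);
  return dX;
}

// in-place-style ReLU product: dY * (Y > 0)
// [[Rcpp::export]]
NumericVector cpp_relu_backward(NumericVector dY, NumericVector Y) {
  NumericVector out(clone(dY));
  for (R_xlen_t i = 0; i < Y.size(); ++i) {
    if (Y[i] <= 0) out[i] = 0;
  }
  out.attr("dim") = dY.attr("dim");
  return out;
}
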