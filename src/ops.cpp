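// Hot inner kernels for the CNN layers: zero-padding gather/scatter,
// im2col/col2im, batch norm, ReLU and max pooling. The layer logic and all
// shapes live in R (nn-layers.R); these functions only move memory and do
// elementwise math, with the matrix products delegated to the BLAS via
// Armadillo. Indices arrive 1-based from R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat view(NumericMatrix X) {
  return arma::mat(X.begin(), X.nrow(), X.ncol(), false, true);
}

// scatter rows of X into a fill-valued (rows x C) matrix at `interior`
// [[Rcpp::export]]
NumericMatrix cpp_pad_rows(NumericMatrix X, IntegerVector interior,
                           int padded_rows, double fill) {
  int C = X.ncol();
  NumericMatrix out(padded_rows, C);
  if (fill != 0.0) std::fill(out.begin(), out.end(), fill);
  for (int c = 0; c < C; ++c) {
    const double* src = &X(0, c);
    double* dst = &out(0, c);
    for (int r = 0; r < X.nrow(); ++r) dst[interior[r] - 1] = src[r];
  }
  return out;
}

// gather rows `interior` from a padded matrix
// [[Rcpp::export]]
NumericMatrix cpp_unpad_rows(NumericMatrix Xp, IntegerVector interior) {
  int C = Xp.ncol(), n = interior.size();
  NumericMatrix out(n, C);
  for (int c = 0; c < C; ++c) {
    const double* src = &Xp(0, c);
    double* dst = &out(0, c);
    for (int r = 0; r < n; ++r) dst[r] = src[interior[r] - 1];
  }
  return out;
}

// im2col + gemm: offsets is (kk x L), P is (L x kk*C), Y = P * W
// [[Rcpp::export]]
List cpp_conv_fwd(NumericMatrix Xp, NumericMatrix W, IntegerMatrix offsets) {
  int kk = offsets.nrow();
  int L = offsets.ncol();
  int C = Xp.ncol();
  NumericMatrix P(L, kk * C);
  for (int o = 0; o < kk; ++o) {
    for (int c = 0; c < C; ++c) {
      const double* src = &Xp(0, c);
      double* dst = &P(0, o * C + c);
      const int* idx = &offsets(o, 0);
      for (int r = 0; r < L; ++r) dst[r] = src[idx[(size_t)r * kk] - 1];
    }
  }
  arma::mat Pm = view(P), Wm = view(W);
  NumericMatrix Y(L, W.ncol());
  arma::mat Ym(Y.begin(), L, W.ncol(), false, true);
  Ym = Pm * Wm;
  return List::create(_["out"] = Y, _["P"] = P);
}

// gradients: dW = P' dY, dXp = col2im(dY W')
// [[Rcpp::export]]
List cpp_conv_bwd(NumericMatrix dY, NumericMatrix P, NumericMatrix W,
                  IntegerMatrix offsets, int padded_rows) {
  int kk = offsets.nrow();
  int L = offsets.ncol();
  int C = W.nrow() / kk;
  arma::mat dYm = view(dY), Pm = view(P), Wm = view(W);
  NumericMatrix dW(W.nrow(), W.ncol());
  arma::mat dWm(dW.begin(), W.nrow(), W.ncol(), false, true);
  dWm = Pm.t() * dYm;
  arma::mat dP = dYm * Wm.t();
  NumericMatrix dXp(padded_rows, C);
  for (int o = 0; o < kk; ++o) {
    for (int c = 0; c < C; ++c) {
      const double* src = dP.colptr(o * C + c);
      double* dst = &dXp(0, c);
      const int* idx = &offsets(o, 0);
      for (int r = 0; r < L; ++r) dst[idx[(size_t)r * kk] - 1] += src[r];
    }
  }
  return List::create(_["dW"] = dW, _["dXp"] = dXp);
}

// batch norm given channel statistics; returns out and xhat
// [[Rcpp::export]]
List cpp_bn_apply(NumericMatrix X, NumericVector gamma, NumericVector beta,
                  NumericVector mu, NumericVector invstd) {
  int m = X.nrow(), C = X.ncol();
  NumericMatrix out(m, C), xhat(m, C);
  for (int c = 0; c < C; ++c) {
    const double* src = &X(0, c);
    double* xh = &xhat(0, c);
    double* y = &out(0, c);
    double mc = mu[c], ic = invstd[c], gc = gamma[c], bc = beta[c];
    for (int r = 0; r < m; ++r) {
      double v = (src[r] - mc) * ic;
      xh[r] = v;
      y[r] = v * gc + bc;
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat);
}

// training-mode batch norm backward
// [[Rcpp::export]]
List cpp_bn_bwd(NumericMatrix dY, NumericMatrix xhat, NumericVector gamma,
                NumericVector invstd, bool batch_stats) {
  int m = dY.nrow(), C = dY.ncol();
  NumericMatrix dX(m, C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* dy = &dY(0, c);
    const double* xh = &xhat(0, c);
    double* dx = &dX(0, c);
    double s1 = 0.0, s2 = 0.0, sg = 0.0, sb = 0.0;
    for (int r = 0; r < m; ++r) {
      sg += dy[r] * xh[r];
      sb += dy[r];
    }
    dgamma[c] = sg;
    dbeta[c] = sb;
    double gc = gamma[c], ic = invstd[c];
    if (batch_stats) {
      s1 = gc * sb / m;
      s2 = gc * sg / m;
      for (int r = 0; r < m; ++r)
        dx[r] = (gc * dy[r] - s1 - xh[r] * s2) * ic;
    } else {
      for (int r = 0; r < m; ++r) dx[r] = gc * dy[r] * ic;
    }
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericMatrix cpp_relu_fwd(NumericMatrix X) {
  NumericMatrix out(X.nrow(), X.ncol());
  std::transform(X.begin(), X.end(), out.begin(),
                 [](double v) { return v > 0.0 ? v : 0.0; });
  return out;
}

// mask taken from the forward output (out > 0 iff x > 0)
// [[Rcpp::export]]
NumericMatrix cpp_relu_bwd(NumericMatrix dY, NumericMatrix out) {
  NumericMatrix dX(dY.nrow(), dY.ncol());
  for (R_xlen_t i = 0; i < dY.size(); ++i)
    dX[i] = out[i] > 0.0 ? dY[i] : 0.0;
  return dX;
}

// max pool over kk offset slices of the (-inf padded) input
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericMatrix Xp, IntegerMatrix offsets) {
  int kk = offsets.nrow();
  int L = offsets.ncol();
  int C = Xp.ncol();
  NumericMatrix out(L, C);
  IntegerMatrix argm(L, C);
  for (int c = 0; c < C; ++c) {
    const double* src = &Xp(0, c);
    double* y = &out(0, c);
    int* am = &argm(0, c);
    for (int r = 0; r < L; ++r) {
      const int* idx = &offsets(0, (size_t)r);
      double best = src[idx[0] - 1];
      int besto = 0;
      for (int o = 1; o < kk; ++o) {
        double v = src[idx[o] - 1];
        if (v > best) { best = v; besto = o; }
      }
      y[r] = best;
      am[r] = besto;
    }
  }
  return List::create(_["out"] = out, _["argm"] = argm);
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool_bwd(NumericMatrix dY, IntegerMatrix argm,
                              IntegerMatrix offsets, int padded_rows) {
  int L = offsets.ncol();
  int C = dY.ncol();
  NumericMatrix dXp(padded_rows, C);
  for (int c = 0; c < C; ++c) {
    const double* dy = &dY(0, c);
    const int* am = &argm(0, c);
    double* dst = &dXp(0, c);
    for (int r = 0; r < L; ++r) {
      const int* idx = &offsets(0, (size_t)r);
      dst[idx[am[r]] - 1] += dy[r];
    }
  }
  return dXp;
}
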