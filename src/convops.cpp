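// Compiled hot paths for the 1-D convolution engine: im2col + BLAS-backed
// matrix products for the convolution forward/backward passes, and direct
// max-pooling. Arrays use R's column-major layout with dimensions
// (batch, length, channels).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Gather the im2col matrix: rows index (batch, out-position), columns index
// (kernel offset, channel); both groupings match R's column-major reshapes.
static arma::mat im2col(const double *x, int n, int L, int C, int k,
                        int stride, int Lo) {
  arma::mat M(static_cast<arma::uword>(n) * Lo, static_cast<arma::uword>(k) * C);
  for (int c = 0; c < C; ++c) {
    for (int kk = 0; kk < k; ++kk) {
      double *dst = M.colptr(static_cast<arma::uword>(c) * k + kk);
      for (int t = 0; t < Lo; ++t) {
        const double *src = x + (static_cast<R_xlen_t>(c) * L + t * stride + kk) * n;
        std::copy(src, src + n, dst + static_cast<R_xlen_t>(t) * n);
      }
    }
  }
  return M;
}

// X: (n, L, C), W: (k, C, F), b: length F. Returns pre-activation (n, Lo, F)
// and the cached im2col matrix for the backward pass.
// [[Rcpp::export(name = ".conv1d_fwd")]]
List conv1d_fwd(NumericVector X, IntegerVector xdim,
                NumericVector W, IntegerVector wdim,
                NumericVector b, int stride, bool use_bias) {
  const int n = xdim[0], L = xdim[1], C = xdim[2];
  const int k = wdim[0], F = wdim[2];
  const int Lo = (L - k) / stride + 1;
  arma::mat M = im2col(X.begin(), n, L, C, k, stride, Lo);
  // W is (k, C, F) with k fastest: rows of the weight matrix are (k, C)
  arma::mat Wm(const_cast<double *>(W.begin()),
               static_cast<arma::uword>(k) * C, F, false, true);
  arma::mat Y = M * Wm;
  if (use_bias) Y.each_row() += arma::rowvec(b.begin(), F);
  NumericVector pre(Y.begin(), Y.end());
  pre.attr("dim") = IntegerVector::create(n, Lo, F);
  NumericMatrix Mout(M.n_rows, M.n_cols, M.begin());
  return List::create(_["pre"] = pre, _["M"] = Mout);
}

// dPre: (n, Lo, F); M: cached im2col. Returns dX (n, L, C), dW (k, C, F), db.
// [[Rcpp::export(name = ".conv1d_bwd")]]
List conv1d_bwd(NumericMatrix M, IntegerVector xdim,
                NumericVector W, IntegerVector wdim,
                NumericVector dPre, int stride) {
  const int n = xdim[0], L = xdim[1], C = xdim[2];
  const int k = wdim[0], F = wdim[2];
  const int Lo = (L - k) / stride + 1;
  arma::mat Mm(M.begin(), M.nrow(), M.ncol(), false, true);
  arma::mat Wm(const_cast<double *>(W.begin()),
               static_cast<arma::uword>(k) * C, F, false, true);
  arma::mat dY(dPre.begin(), static_cast<arma::uword>(n) * Lo, F, false, true);
  arma::mat dWm = Mm.t() * dY;                 // (k*C, F)
  arma::mat dM = dY * Wm.t();                  // (n*Lo, k*C)
  NumericVector dX(static_cast<R_xlen_t>(n) * L * C);
  double *dx = dX.begin();
  for (int c = 0; c < C; ++c) {
    for (int kk = 0; kk < k; ++kk) {
      const double *src = dM.colptr(static_cast<arma::uword>(c) * k + kk);
      for (int t = 0; t < Lo; ++t) {
        double *dst = dx + (static_cast<R_xlen_t>(c) * L + t * stride + kk) * n;
        const double *s = src + static_cast<R_xlen_t>(t) * n;
        for (int i = 0; i < n; ++i) dst[i] += s[i];
      }
    }
  }
  dX.attr("dim") = IntegerVector::create(n, L, C);
  NumericVector dW(dWm.begin(), dWm.end());
  dW.attr("dim") = IntegerVector::create(k, C, F);
  NumericVector db(F);
  for (int f = 0; f < F; ++f) db[f] = arma::accu(dY.col(f));
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// X: (n, L, C), pool width p (stride p). Returns Y (n, Lo, C) and argmax offsets.
// [[Rcpp::export(name = ".maxpool_fwd")]]
List maxpool_fwd(NumericVector X, IntegerVector xdim, int p) {
  const int n = xdim[0], L = xdim[1], C = xdim[2];
  const int Lo = (L - p) / p + 1;
  NumericVector Y(static_cast<R_xlen_t>(n) * Lo * C);
  IntegerVector AM(static_cast<R_xlen_t>(n) * Lo * C);
  const double *x = X.begin();
  double *y = Y.begin();
  int *am = AM.begin();
  for (int c = 0; c < C; ++c) {
    for (int t = 0; t < Lo; ++t) {
      const R_xlen_t yoff = (static_cast<R_xlen_t>(c) * Lo + t) * n;
      for (int i = 0; i < n; ++i) {
        double best = x[i + (static_cast<R_xlen_t>(c) * L + t * p) * n];
        int bj = 0;
        for (int j = 1; j < p; ++j) {
          const double v = x[i + (static_cast<R_xlen_t>(c) * L + t * p + j) * n];
          if (v > best) { best = v; bj = j; }
        }
        y[yoff + i] = best;
        am[yoff + i] = bj;
      }
    }
  }
  Y.attr("dim") = IntegerVector::create(n, Lo, C);
  AM.attr("dim") = IntegerVector::create(n, Lo, C);
  return List::create(_["Y"] = Y, _["AM"] = AM);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
NumericVector maxpool_bwd(NumericVector dY, IntegerVector AM,
                          IntegerVector ydim, int p, int L) {
  const int n = ydim[0], Lo = ydim[1], C = ydim[2];
  NumericVector dX(static_cast<R_xlen_t>(n) * L * C);
  const double *dy = dY.begin();
  const int *am = AM.begin();
  double *dx = dX.begin();
  for (int c = 0; c < C; ++c) {
    for (int t = 0; t < Lo; ++t) {
      const R_xlen_t yoff = (static_cast<R_xlen_t>(c) * Lo + t) * n;
      for (int i = 0; i < n; ++i) {
        dx[i + (static_cast<R_xlen_t>(c) * L + t * p + am[yoff + i]) * n] += dy[yoff + i];
      }
    }
  }
  dX.attr("dim") = IntegerVector::create(n, L, C);
  return dX;
}
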