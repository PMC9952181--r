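#include <RcppArmadillo.h>
using namespace Rcpp;

// 1-D valid convolution and max-pooling kernels for the training engine.
// Arrays are batch-major, matching R's (batch, time, channel) layout;
// the im2col matrix product runs through BLAS.

static arma::mat im2col(const arma::cube &X, int k) {
  const int B = X.n_rows, L = X.n_cols, C = X.n_slices;
  const int Lout = L - k + 1;
  arma::mat Xcol(B * Lout, k * C);
  for (int o = 0; o < k; ++o) {
    for (int c = 0; c < C; ++c) {
      double *dst = Xcol.colptr(o * C + c);
      for (int t = 0; t < Lout; ++t) {
        std::memcpy(dst + (size_t)t * B, X.slice_colptr(c, t + o),
                    B * sizeof(double));
      }
    }
  }
  return Xcol;
}

// [[Rcpp::export(name = ".conv1d_fwd_cpp")]]
NumericVector conv1d_fwd_cpp(NumericVector Xv, NumericMatrix Wm,
                             NumericVector bv) {
  IntegerVector dims = Xv.attr("dim");
  const int B = dims[0], L = dims[1], C = dims[2];
  const arma::cube X(const_cast<double *>(Xv.begin()), B, L, C, false);
  const arma::mat W(const_cast<double *>(Wm.begin()), Wm.nrow(), Wm.ncol(),
                    false);
  const int k = Wm.nrow() / C, F = Wm.ncol(), Lout = L - k + 1;
  arma::mat Y = im2col(X, k) * W;
  Y.each_row() += arma::rowvec(const_cast<double *>(bv.begin()), F, false);
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(B, Lout, F);
  return out;
}

// [[Rcpp::export(name = ".conv1d_bwd_cpp")]]
List conv1d_bwd_cpp(NumericVector Xv, NumericMatrix Wm, NumericVector dYv) {
  IntegerVector dims = Xv.attr("dim");
  const int B = dims[0], L = dims[1], C = dims[2];
  const arma::cube X(const_cast<double *>(Xv.begin()), B, L, C, false);
  const arma::mat W(const_cast<double *>(Wm.begin()), Wm.nrow(), Wm.ncol(),
                    false);
  const int k = Wm.nrow() / C, F = Wm.ncol(), Lout = L - k + 1;
  const arma::mat dY(const_cast<double *>(dYv.begin()), B * Lout, F, false);
  arma::mat Xcol = im2col(X, k);
  arma::mat dW = Xcol.t() * dY;
  arma::rowvec db = arma::sum(dY, 0);
  arma::mat dXcol = dY * W.t();
  arma::cube dX(B, L, C, arma::fill::zeros);
  for (int o = 0; o < k; ++o) {
    for (int c = 0; c < C; ++c) {
      const double *src = dXcol.colptr(o * C + c);
      for (int t = 0; t < Lout; ++t) {
        double *dst = dX.slice_colptr(c, t + o);
        const double *s = src + (size_t)t * B;
        for (int b = 0; b < B; ++b) dst[b] += s[b];
      }
    }
  }
  NumericVector dXout(dX.begin(), dX.end());
  dXout.attr("dim") = IntegerVector::create(B, L, C);
  return List::create(_["dX"] = dXout,
                      _["dW"] = NumericMatrix(dW.n_rows, dW.n_cols,
                                              dW.begin()),
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export(name = ".maxpool_fwd_cpp")]]
List maxpool_fwd_cpp(NumericVector Xv) {
  IntegerVector dims = Xv.attr("dim");
  const int B = dims[0], L = dims[1], C = dims[2];
  const int L2 = L / 2;
  const double *x = Xv.begin();
  NumericVector Y((size_t)B * L2 * C);
  LogicalVector sel2((size_t)B * L2 * C);
  double *y = Y.begin();
  int *s2 = sel2.begin();
  for (int c = 0; c < C; ++c) {
    for (int t = 0; t < L2; ++t) {
      const double *x1 = x + (size_t)c * B * L + (size_t)(2 * t) * B;
      const double *x2 = x1 + B;
      double *yo = y + (size_t)c * B * L2 + (size_t)t * B;
      int *so = s2 + (size_t)c * B * L2 + (size_t)t * B;
      for (int b = 0; b < B; ++b) {
        if (x2[b] > x1[b]) {
          yo[b] = x2[b];
          so[b] = 1;
        } else {
          yo[b] = x1[b];
          so[b] = 0;
        }
      }
    }
  }
  Y.attr("dim") = IntegerVector::create(B, L2, C);
  sel2.attr("dim") = IntegerVector::create(B, L2, C);
  return List::create(_["Y"] = Y, _["sel2"] = sel2);
}

// [[Rcpp::export(name = ".maxpool_bwd_cpp")]]
NumericVector maxpool_bwd_cpp(NumericVector dYv, LogicalVector sel2,
                              int L) {
  IntegerVector dims = dYv.attr("dim");
  const int B = dims[0], L2 = dims[1], C = dims[2];
  NumericVector dX((size_t)B * L * C);
  const double *dy = dYv.begin();
  const int *s2 = sel2.begin();
  double *dx = dX.begin();
  for (int c = 0; c < C; ++c) {
    for (int t = 0; t < L2; ++t) {
      const double *dyo = dy + (size_t)c * B * L2 + (size_t)t * B;
      const int *so = s2 + (size_t)c * B * L2 + (size_t)t * B;
      double *dx1 = dx + (size_t)c * B * L + (size_t)(2 * t) * B;
      double *dx2 = dx1 + B;
      for (int b = 0; b < B; ++b) {
        if (so[b]) dx2[b] = dyo[b];
        else dx1[b] = dyo[b];
      }
    }
  }
  dX.attr("dim") = IntegerVector::create(B, L, C);
  return dX;
}
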