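// Core of the AA-gapped convolution: shifted matrix products evaluated by
// BLAS dgemm on offset column pointers, so no shifted copies are made.
//
// Layout: activations are (channels x M) with M = shift_unit * bins and
// columns ordered sample-fastest (column = n + shift_unit * (bin - 1)).
// A shift by one 1-Da bin is then a global column offset of `shift_unit`,
// and zero padding falls out of the truncated column ranges.
//
// Per dilation m the weight matrix Wd[j] is (c_out x 2 c_in): the first
// c_in columns are the tap at bin - m, the last c_in the tap at bin + m.

#include <Rcpp.h>
#include <R_ext/BLAS.h>

using namespace Rcpp;

static inline void dgemm(const char* ta, const char* tb, int m, int n,
                         int k, double alpha, const double* A, int lda,
                         const double* B, int ldb, double beta, double* C,
                         int ldc) {
  F77_CALL(dgemm)(ta, tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C,
                  &ldc FCONE FCONE);
}

// [[Rcpp::export]]
NumericMatrix cpp_gconv_forward(const NumericMatrix& X,
                                const NumericMatrix& W0, const List& Wd,
                                const NumericVector& b,
                                const IntegerVector& dil,
                                const int shift_unit) {
  const int C = X.nrow();
  const int M = X.ncol();
  const int Cout = W0.nrow();
  NumericMatrix Y(Cout, M);
  for (int i = 0; i < M; ++i)
    for (int c = 0; c < Cout; ++c) Y(c, i) = b[c];
  // center tap
  dgemm("N", "N", Cout, M, C, 1.0, W0.begin(), Cout, X.begin(), C, 1.0,
        Y.begin(), Cout);
  for (int j = 0; j < dil.size(); ++j) {
    const int s = dil[j] * shift_unit;
    if (s >= M) continue;
    NumericMatrix W = Wd[j];
    const double* Wm = W.begin();
    const double* Wp = W.begin() + (R_xlen_t)C * Cout;
    // Y[, s:M) += Wm * X[, 0:M-s)
    dgemm("N", "N", Cout, M - s, C, 1.0, Wm, Cout, X.begin(), C, 1.0,
          Y.begin() + (R_xlen_t)s * Cout, Cout);
    // Y[, 0:M-s) += Wp * X[, s:M)
    dgemm("N", "N", Cout, M - s, C, 1.0, Wp, Cout,
          X.begin() + (R_xlen_t)s * C, C, 1.0, Y.begin(), Cout);
  }
  return Y;
}

// [[Rcpp::export]]
List cpp_gconv_backward(const NumericMatrix& dY, const NumericMatrix& X,
                        const NumericMatrix& W0, const List& Wd,
                        const IntegerVector& dil, const int shift_unit) {
  const int C = X.nrow();
  const int M = X.ncol();
  const int Cout = dY.nrow();
  NumericMatrix dX(C, M);
  NumericMatrix gW0(Cout, C);
  NumericVector gb(Cout);
  for (int i = 0; i < M; ++i)
    for (int c = 0; c < Cout; ++c) gb[c] += dY(c, i);
  // dX += W0' dY ; gW0 = dY X'
  dgemm("T", "N", C, M, Cout, 1.0, W0.begin(), Cout, dY.begin(), Cout, 0.0,
        dX.begin(), C);
  dgemm("N", "T", Cout, C, M, 1.0, dY.begin(), Cout, X.begin(), C, 0.0,
        gW0.begin(), Cout);
  List gWd(dil.size());
  for (int j = 0; j < dil.size(); ++j) {
    const int s = dil[j] * shift_unit;
    NumericMatrix W = Wd[j];
    NumericMatrix g(Cout, 2 * C);
    if (s < M) {
      const double* Wm = W.begin();
      const double* Wp = W.begin() + (R_xlen_t)C * Cout;
      // dX[, 0:M-s) += Wm' dY[, s:M) ; dX[, s:M) += Wp' dY[, 0:M-s)
      dgemm("T", "N", C, M - s, Cout, 1.0, Wm, Cout,
            dY.begin() + (R_xlen_t)s * Cout, Cout, 1.0, dX.begin(), C);
      dgemm("T", "N", C, M - s, Cout, 1.0, Wp, Cout, dY.begin(), Cout, 1.0,
            dX.begin() + (R_xlen_t)s * C, C);
      // gWm = dY[, s:M) X[, 0:M-s)' ; gWp = dY[, 0:M-s) X[, s:M)'
      dgemm("N", "T", Cout, C, M - s, 1.0,
            dY.begin() + (R_xlen_t)s * Cout, Cout, X.begin(), C, 0.0,
            g.begin(), Cout);
      dgemm("N", "T", Cout, C, M - s, 1.0, dY.begin(), Cout,
            X.begin() + (R_xlen_t)s * C, C, 0.0,
            g.begin() + (R_xlen_t)C * Cout, Cout);
    }
    gWd[j] = g;
  }
  return List::create(Named("dX") = dX, Named("W0") = gW0,
                      Named("Wd") = gWd, Named("b") = gb);
}
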