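// Sparse (CSC) times dense multiply returning a plain matrix, avoiding the
// S4 round-trips of Matrix dispatch in the training inner loop. The dense
// operand is passed as a flat vector with an explicit column count so
// callers can reinterpret (V*B) x C batches as V x (B*C) without copying;
// columns are processed in blocks of 8 to amortise index loads. The kernel
// computes out = alpha * A %*% B + beta * C0 in one pass (C0 optional), so
// the Chebyshev recursion needs no intermediate temporaries.
#include <Rcpp.h>
#include <algorithm>
#include <cstring>
using namespace Rcpp;

// [[Rcpp::export(name = ".spmm_cpp")]]
NumericVector spmm_cpp(IntegerVector p, IntegerVector i, NumericVector x,
                       int nrow, NumericVector bvec, int bncol,
                       double alpha = 1.0,
                       Nullable<NumericVector> init = R_NilValue,
                       double beta = 1.0) {
  const int ncolA = p.size() - 1;
  if ((R_xlen_t)ncolA * bncol != bvec.size())
    stop("dimension mismatch in sparse multiply");
  NumericVector out((R_xlen_t)nrow * bncol);
  double* yp = REAL(out);
  if (init.isNotNull()) {
    NumericVector c0(init);
    if (c0.size() != out.size()) stop("init length mismatch");
    const double* cp = REAL(c0);
    if (beta == 1.0) {
      std::memcpy(yp, cp, sizeof(double) * out.size());
    } else {
      for (R_xlen_t k = 0; k < out.size(); ++k) yp[k] = beta * cp[k];
    }
  }
  const double* bp = REAL(bvec);
  const int* pp = INTEGER(p);
  const int* ip = INTEGER(i);
  const double* xp = REAL(x);
  const int BLK = 8;
  for (int c0 = 0; c0 < bncol; c0 += BLK) {
    const int cb = std::min(BLK, bncol - c0);
    const double* bcol[BLK];
    double* ycol[BLK];
    for (int cc = 0; cc < cb; ++cc) {
      bcol[cc] = bp + (R_xlen_t)(c0 + cc) * ncolA;
      ycol[cc] = yp + (R_xlen_t)(c0 + cc) * nrow;
    }
    for (int j = 0; j < ncolA; ++j) {
      double bv[BLK];
      bool any = false;
      for (int cc = 0; cc < cb; ++cc) {
        bv[cc] = alpha * bcol[cc][j];
        if (bv[cc] != 0.0) any = true;
      }
      if (!any) continue;
      const int kend = pp[j + 1];
      if (cb == BLK) {
        for (int k = pp[j]; k < kend; ++k) {
          const int r = ip[k];
          const double v = xp[k];
          ycol[0][r] += v * bv[0]; ycol[1][r] += v * bv[1];
          ycol[2][r] += v * bv[2]; ycol[3][r] += v * bv[3];
          ycol[4][r] += v * bv[4]; ycol[5][r] += v * bv[5];
          ycol[6][r] += v * bv[6]; ycol[7][r] += v * bv[7];
        }
      } else {
        for (int k = pp[j]; k < kend; ++k) {
          const int r = ip[k];
          const double v = xp[k];
          for (int cc = 0; cc < cb; ++cc) ycol[cc][r] += v * bv[cc];
        }
      }
    }
  }
  return out;
}

// y += bias[col] in place; y is a freshly allocated GEMM result.
// [[Rcpp::export(name = ".add_bias_cpp")]]
NumericMatrix add_bias_cpp(NumericMatrix y, NumericVector bias) {
  if (bias.size() != y.ncol()) stop("bias length mismatch");
  double* p = REAL(y);
  const int nr = y.nrow();
  for (int c = 0; c < y.ncol(); ++c) {
    const double b = bias[c];
    double* col = p + (R_xlen_t)c * nr;
    for (int r = 0; r < nr; ++r) col[r] += b;
  }
  return y;
}
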