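// Exponential linear unit and its backward pass, applied in one sweep to
// avoid repeated large temporaries in the training loop.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".elu_cpp")]]
NumericVector elu_cpp(NumericVector x) {
  NumericVector y = clone(x);
  double* p = REAL(y);
  const R_xlen_t n = y.size();
  for (R_xlen_t i = 0; i < n; ++i)
    if (p[i] < 0) p[i] = std::exp(p[i]) - 1.0;
  return y;
}

// dX = dY * elu'(x) with elu'(x) recovered from the activation output:
// 1 where y > 0, y + 1 elsewhere.
// [[Rcpp::export(name = ".elu_backward_cpp")]]
NumericVector elu_backward_cpp(NumericVector dy, NumericVector y) {
  if (dy.size() != y.size()) stop("length mismatch");
  NumericVector out = clone(dy);
  double* p = REAL(out);
  const double* yp = REAL(y);
  const R_xlen_t n = out.size();
  for (R_xlen_t i = 0; i < n; ++i)
    if (yp[i] <= 0) p[i] *= yp[i] + 1.0;
  return out;
}
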