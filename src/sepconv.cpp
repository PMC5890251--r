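#include <Rcpp.h>
using namespace Rcpp;

// Separable 2-D correlation with an odd-length 1-D kernel and zero padding.
// The kernel is applied along rows and then along columns; for the symmetric
// kernels used throughout (Gaussian), correlation equals convolution.
// Zero padding is load-bearing: the energy's local terms are double sums over
// the image domain only, and the analytic gradient assumes exactly that.
// [[Rcpp::export]]
NumericMatrix sepconv2_cpp(NumericMatrix x, NumericVector k) {
  const int nr = x.nrow(), nc = x.ncol(), L = k.size(), c = L / 2;
  if (L % 2 == 0) stop("kernel length must be odd");
  NumericMatrix tmp(nr, nc), out(nr, nc);

  // vertical pass (along each column)
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const int t0 = std::max(0, c - i), t1 = std::min(L, nr + c - i);
      double s = 0.0;
      for (int t = t0; t < t1; ++t) s += k[t] * x(i + t - c, j);
      tmp(i, j) = s;
    }
  }
  // horizontal pass (along each row)
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      const int t0 = std::max(0, c - j), t1 = std::min(L, nc + c - j);
      double s = 0.0;
      for (int t = t0; t < t1; ++t) s += k[t] * tmp(i, j + t - c);
      out(i, j) = s;
    }
  }
  return out;
}
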