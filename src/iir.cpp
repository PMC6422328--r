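#include <Rcpp.h>
using namespace Rcpp;

// Causal IIR filter (direct form II transposed, zero initial state) applied
// down each column of X. Coefficients are normalized by a[0]. This is the
// kernel under the zero-phase (forward-backward) band-pass used throughout
// the decoder; the R wrapper adds the padding and reversal.
// [[Rcpp::export]]
NumericMatrix iir_filter_mat(NumericVector b, NumericVector a,
                             NumericMatrix X) {
  int m = std::max(b.size(), a.size());
  std::vector<double> bb(m, 0.0), aa(m, 0.0);
  double a0 = a[0];
  for (int k = 0; k < b.size(); ++k) bb[k] = b[k] / a0;
  for (int k = 0; k < a.size(); ++k) aa[k] = a[k] / a0;
  int n = X.nrow(), p = X.ncol();
  NumericMatrix Y(n, p);
  std::vector<double> z(m - 1);
  for (int j = 0; j < p; ++j) {
    std::fill(z.begin(), z.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      double x = X(i, j);
      double y = bb[0] * x + z[0];
      for (int k = 1; k < m - 1; ++k)
        z[k - 1] = bb[k] * x + z[k] - aa[k] * y;
      z[m - 2] = bb[m - 1] * x - aa[m - 1] * y;
      Y(i, j) = y;
    }
  }
  return Y;
}
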