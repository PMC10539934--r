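#include <Rcpp.h>
using namespace Rcpp;

// Template match counts for sample entropy with Chebyshev distance and an
// absolute tolerance. Counts unordered pairs (i < j) of templates of length
// m and m+1 that match within r; self-matches are excluded by construction.
// Returns c(B, A) = (m-matches, (m+1)-matches).
// [[Rcpp::export(name = ".sampen_counts")]]
NumericVector sampen_counts(NumericVector y, int m, double r) {
  const int n = y.size();
  const int nm = n - m;          // number of templates of length m+1
  double B = 0.0, A = 0.0;
  // pairs over templates of length m (indices 0..n-m-? ): follow the
  // convention of counting only the N-m templates that can be extended,
  // so that C_m and C_{m+1} are built from the same template set.
  for (int i = 0; i < nm - 1; ++i) {
    for (int j = i + 1; j < nm; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dk = std::fabs(y[i + k] - y[j + k]);
        if (dk > d) d = dk;
      }
      if (d <= r) {
        B += 1.0;
        if (std::fabs(y[i + m] - y[j + m]) <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(B, A);
}
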