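#include <Rcpp.h>
using namespace Rcpp;

// Count similar template pairs for sample entropy.
// Both template lengths use the same T - m templates so that a constant
// series yields A == B and SampEn == 0 exactly. Chebyshev distance,
// closed inequality (<= r), self-matches excluded, unordered pairs.
// [[Rcpp::export(name = ".sampenCounts")]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int T = x.size();
  const int n = T - m;  // templates usable at both lengths
  double A = 0.0, B = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double diff = std::fabs(x[i + k] - x[j + k]);
        if (diff > d) d = diff;
        if (d > r) break;
      }
      if (d <= r) {
        B += 1.0;
        double diff = std::fabs(x[i + m] - x[j + m]);
        if (diff <= r && d <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(_["A"] = A, _["B"] = B);
}
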