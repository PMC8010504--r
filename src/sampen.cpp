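#include <Rcpp.h>
using namespace Rcpp;

// Sample entropy, embedding m, tolerance r, Chebyshev distance,
// self-matches excluded.  Counts template matches at length m (B) and
// m+1 (A); SampEn = -log(A/B).
// [[Rcpp::export]]
List sampen_counts(NumericVector x, int m, double r) {
  int n = x.size();
  long long A = 0, B = 0;
  for (int i = 0; i < n - m; ++i) {
    for (int j = i + 1; j < n - m; ++j) {
      double d = 0.0;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        double dk = std::fabs(x[i + k] - x[j + k]);
        if (dk > d) d = dk;
        if (d > r) { ok = false; break; }
      }
      if (!ok) continue;
      ++B;
      double dk = std::fabs(x[i + m] - x[j + m]);
      if (dk <= r && d <= r) ++A;
    }
  }
  return List::create(Named("A") = (double)A, Named("B") = (double)B);
}
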