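#include <Rcpp.h>
using namespace Rcpp;

// Sample entropy: -log(A/B) with Chebyshev distance, self-matches excluded.
// B = matching template pairs of length m, A = pairs still matching at m+1.
// Counts ordered pairs i<j once each, the standard convention.
// [[Rcpp::export]]
List sampen_counts(NumericVector x, int m, double r) {
  int n = x.size();
  long long A = 0, B = 0;
  int nm = n - m;  // number of m+1-length templates is nm; m-length is nm+1
  // iterate over template start pairs (i, j), i < j, for templates of length m
  // restricted to starts <= n - m - 1 for the A count
  for (int i = 0; i < n - m; ++i) {
    for (int j = i + 1; j < n - m; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::abs(x[i + k] - x[j + k]) > r) { match = false; break; }
      }
      if (match) {
        ++B;
        if (std::abs(x[i + m] - x[j + m]) <= r) ++A;
      }
    }
  }
  (void)nm;
  return List::create(_["A"] = (double)A, _["B"] = (double)B);
}
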