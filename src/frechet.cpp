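#include <Rcpp.h>
using namespace Rcpp;

// Discrete Frechet distance between two 2-D point sequences by the
// standard O(nm) dynamic program over monotone couplings.
// [[Rcpp::export(name = ".frechet_dp")]]
double frechet_dp(NumericMatrix a, NumericMatrix b) {
  int n = a.nrow(), m = b.nrow();
  std::vector<double> prev(m), cur(m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double dx = a(i, 0) - b(j, 0), dy = a(i, 1) - b(j, 1);
      double d = std::sqrt(dx * dx + dy * dy);
      double best;
      if (i == 0 && j == 0) best = d;
      else if (i == 0) best = std::max(cur[j - 1], d);
      else if (j == 0) best = std::max(prev[0], d);
      else {
        double m3 = std::min(prev[j], std::min(cur[j - 1], prev[j - 1]));
        best = std::max(m3, d);
      }
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}
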