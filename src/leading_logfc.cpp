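#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Pairwise leading log-fold-change distance: for each pair of columns of
// `x` (genes x cells), the root mean square of the k largest absolute
// per-gene differences. k is clamped to the number of genes.
// [[Rcpp::export]]
NumericMatrix pairwise_leading_rms(NumericMatrix x, int k) {
  const int g = x.nrow(), n = x.ncol();
  if (k < 1) stop("k_top must be >= 1");
  const int kk = std::min(k, g);
  NumericMatrix d(n, n);
  std::vector<double> buf(g);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      for (int t = 0; t < g; ++t) {
        const double dd = x(t, i) - x(t, j);
        buf[t] = dd * dd;
      }
      std::nth_element(buf.begin(), buf.begin() + (g - kk), buf.end());
      double s = 0.0;
      for (int t = g - kk; t < g; ++t) s += buf[t];
      const double v = std::sqrt(s / kk);
      d(i, j) = v;
      d(j, i) = v;
    }
  }
  return d;
}
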