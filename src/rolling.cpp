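#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Rolling "mean of the bottom fraction" of samples in a centred window.
// For each index i, take the window [i - halfwin, i + halfwin] (truncated at
// the edges), select the floor(frac * m) smallest values (at least min_k),
// and return their mean. This is the percentile-style baseline used to
// separate calcium transients from slow baseline fluctuations.
// [[Rcpp::export]]
NumericVector roll_bottom_mean(NumericVector x, int halfwin, double frac,
                               int min_k) {
  int n = x.size();
  NumericVector out(n);
  std::vector<double> buf;
  buf.reserve(2 * halfwin + 1);
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - halfwin);
    int hi = std::min(n - 1, i + halfwin);
    int m = hi - lo + 1;
    int k = std::max(min_k, (int)std::floor(frac * m));
    if (k > m) k = m;
    buf.assign(x.begin() + lo, x.begin() + hi + 1);
    std::nth_element(buf.begin(), buf.begin() + (k - 1), buf.end());
    double s = 0.0;
    for (int j = 0; j < k; ++j) s += buf[j];
    out[i] = s / k;
  }
  return out;
}
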