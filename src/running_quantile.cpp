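#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sliding-window percentile with edge truncation.
//
// Maintains the window as a sorted vector updated incrementally (binary
// search insert/erase), and interpolates between order statistics with the
// exact arithmetic of stats::quantile type 7 so results are bit-identical
// to a per-frame quantile() call on the truncated window.
//
// x: trace; halfwin: half window in frames; p: probability in (0, 1).
// [[Rcpp::export]]
NumericVector run_quantile_cpp(NumericVector x, int halfwin, double p) {
  const int n = x.size();
  NumericVector out(n);
  if (n == 0) return out;
  if (halfwin < 0) stop("halfwin must be >= 0");

  std::vector<double> w;
  w.reserve(2 * (size_t)halfwin + 2);
  int lo = 0, hi = -1; // current window [lo, hi], inclusive

  for (int t = 0; t < n; ++t) {
    const int nlo = std::max(0, t - halfwin);
    const int nhi = std::min(n - 1, t + halfwin);
    for (int j = hi + 1; j <= nhi; ++j) {
      const double v = x[j];
      if (ISNAN(v)) stop("NA in trace");
      w.insert(std::upper_bound(w.begin(), w.end(), v), v);
    }
    for (int j = lo; j < nlo; ++j) {
      w.erase(std::lower_bound(w.begin(), w.end(), x[j]));
    }
    lo = nlo; hi = nhi;

    const int m = (int)w.size();
    // type-7: index = 1 + (m - 1) * p, interpolate x[floor], x[ceil]
    const double index = 1.0 + (m - 1) * p;
    const int kl = (int)std::floor(index);
    const int kh = (int)std::ceil(index);
    const double vlo = w[kl - 1];
    const double vhi = w[kh - 1];
    if (kh == kl || vhi == vlo) {
      out[t] = vlo;
    } else {
      const double h = index - kl;
      out[t] = (1.0 - h) * vlo + h * vhi;
    }
  }
  return out;
}
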