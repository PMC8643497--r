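#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Centered sliding-window quantile with edge truncation.
// Quantile uses linear interpolation between order statistics (type 7).
// The window is kept as a sorted vector updated incrementally; with window
// w the update is a binary search plus an O(w) memmove, cheap for the
// window sizes used here (<= ~1000 frames).
// [[Rcpp::export(name = ".sliding_quantile_cpp")]]
NumericVector sliding_quantile_cpp(NumericVector x, int window, double prob) {
  const int n = x.size();
  NumericVector out(n);
  if (n == 0) return out;
  const int half_l = (window - 1) / 2;
  const int half_r = window - 1 - half_l;

  std::vector<double> win;
  win.reserve(window + 1);
  int lo = 0, hi = -1; // current window bounds [lo, hi], inclusive

  for (int i = 0; i < n; ++i) {
    int nlo = std::max(0, i - half_l);
    int nhi = std::min(n - 1, i + half_r);
    while (hi < nhi) {
      ++hi;
      win.insert(std::upper_bound(win.begin(), win.end(), x[hi]), x[hi]);
    }
    while (lo < nlo) {
      win.erase(std::lower_bound(win.begin(), win.end(), x[lo]));
      ++lo;
    }
    const int m = static_cast<int>(win.size());
    const double h = (m - 1) * prob;
    const int k = static_cast<int>(std::floor(h));
    double v = win[k];
    if (k + 1 < m) v += (h - k) * (win[k + 1] - win[k]);
    out[i] = v;
  }
  return out;
}
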