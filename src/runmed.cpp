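#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Running median over each row with a centered window of `w` samples;
// at the edges the window shrinks to the valid range. For even in-window
// counts the median is the mean of the two central order statistics.
// [[Rcpp::export]]
NumericMatrix row_running_median(NumericMatrix x, int w) {
  const int n = x.nrow(), T = x.ncol();
  const int lo = (w - 1) / 2, hi = w / 2;  // offsets: t-lo .. t+hi
  NumericMatrix out(n, T);
  std::vector<double> buf;
  buf.reserve(w);
  for (int i = 0; i < n; ++i) {
    for (int t = 0; t < T; ++t) {
      int a = std::max(0, t - lo), b = std::min(T - 1, t + hi);
      buf.assign(x.row(i).begin() + a, x.row(i).begin() + b + 1);
      const int m = (int) buf.size();
      std::nth_element(buf.begin(), buf.begin() + m / 2, buf.end());
      double med = buf[m / 2];
      if (m % 2 == 0) {
        double lo2 = *std::max_element(buf.begin(), buf.begin() + m / 2);
        med = 0.5 * (med + lo2);
      }
      out(i, t) = med;
    }
  }
  return out;
}
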