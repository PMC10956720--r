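#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

static inline int find_bin(double d, const NumericVector& breaks) {
  // bin k (1-based) such that breaks[k-1] < d <= breaks[k]; 0 if outside
  int nb = breaks.size() - 1;
  if (d <= breaks[0] || d > breaks[nb]) return 0;
  int lo = 0, hi = nb;  // invariant: breaks[lo] < d <= breaks[hi]
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (d > breaks[mid]) lo = mid; else hi = mid;
  }
  return hi;
}

static inline bool uniform_breaks(const NumericVector& breaks, double& w) {
  const int nb = breaks.size() - 1;
  w = (breaks[nb] - breaks[0]) / nb;
  if (w <= 0) return false;
  for (int k = 0; k <= nb; ++k)
    if (std::abs(breaks[k] - breaks[0] - k * w) > 1e-9 * (1 + std::abs(breaks[k])))
      return false;
  return true;
}

static inline int find_bin_uniform(double d, double b0, double w, int nb) {
  if (d <= b0) return 0;
  const int k = (int) std::ceil((d - b0) / w - 1e-12);
  return (k >= 1 && k <= nb) ? k : 0;
}

// Per-distance-bin pair statistics over all i < j without materialising the
// pair distance matrix: pair counts and the sums of (a_i + a_j), where a is
// any per-unit quantity. O(N^2) time, O(bins) memory.
// [[Rcpp::export]]
List pair_bin_stats_cpp(NumericVector x, NumericVector y, NumericVector a,
                        NumericVector breaks) {
  const int n = x.size(), nb = breaks.size() - 1;
  NumericVector count(nb), asum(nb);
  double w; const bool uni = uniform_breaks(breaks, w);
  const double b0 = breaks[0];
  for (int i = 0; i < n; ++i) {
    const double xi = x[i], yi = y[i], ai = a[i];
    for (int j = i + 1; j < n; ++j) {
      const double dx = xi - x[j], dy = yi - y[j];
      const double d = std::sqrt(dx * dx + dy * dy);
      const int b = uni ? find_bin_uniform(d, b0, w, nb) : find_bin(d, breaks);
      if (b > 0) { count[b - 1] += 1.0; asum[b - 1] += ai + a[j]; }
    }
  }
  return List::create(_["count"] = count, _["asum"] = asum);
}

// Bin the off-diagonal (i < j) entries of a sparse symmetric cross-product
// given as triplets; returns the per-bin sums of the entry values.
// [[Rcpp::export]]
NumericVector triplet_bin_sums_cpp(IntegerVector ti, IntegerVector tj,
                                   NumericVector tx, NumericVector x,
                                   NumericVector y, NumericVector breaks) {
  const int nb = breaks.size() - 1;
  NumericVector vsum(nb);
  double w; const bool uni = uniform_breaks(breaks, w);
  const double b0 = breaks[0];
  for (int k = 0; k < ti.size(); ++k) {
    const int i = ti[k] - 1, j = tj[k] - 1;
    if (i >= j) continue;
    const double dx = x[i] - x[j], dy = y[i] - y[j];
    const double d = std::sqrt(dx * dx + dy * dy);
    const int b = uni ? find_bin_uniform(d, b0, w, nb) : find_bin(d, breaks);
    if (b > 0) vsum[b - 1] += tx[k];
  }
  return vsum;
}

// Same binned pair sums for a dense symmetric cross-product matrix,
// without materialising pair distances. O(N^2) time, O(bins) memory.
// [[Rcpp::export]]
NumericVector matrix_bin_sums_cpp(NumericMatrix V, NumericVector x,
                                  NumericVector y, NumericVector breaks) {
  const int n = x.size(), nb = breaks.size() - 1;
  NumericVector vsum(nb);
  double w; const bool uni = uniform_breaks(breaks, w);
  const double b0 = breaks[0];
  for (int i = 0; i < n; ++i) {
    const double xi = x[i], yi = y[i];
    for (int j = i + 1; j < n; ++j) {
      const double dx = xi - x[j], dy = yi - y[j];
      const double d = std::sqrt(dx * dx + dy * dy);
      const int b = uni ? find_bin_uniform(d, b0, w, nb) : find_bin(d, breaks);
      if (b > 0) vsum[b - 1] += V(i, j);
    }
  }
  return vsum;
}
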