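#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <map>
#include <vector>
using namespace Rcpp;

// Exact order statistics (0-based ranks) of `v` via a one-pass histogram:
// only the few bins containing the requested ranks are collected and
// sorted. Equivalent to full sorting but linear-time for large vectors.
static std::vector<double> order_stats(const std::vector<double>& v,
                                       const std::vector<size_t>& ranks,
                                       double vmin, double vmax) {
  const size_t n = v.size();
  std::vector<double> out(ranks.size());
  if (vmax <= vmin) {
    std::fill(out.begin(), out.end(), vmin);
    return out;
  }
  const int nbins = 4096;
  const double width = (vmax - vmin) / nbins;
  std::vector<size_t> counts(nbins, 0);
  for (size_t i = 0; i < n; ++i) {
    int b = static_cast<int>((v[i] - vmin) / width);
    if (b >= nbins) b = nbins - 1;
    if (b < 0) b = 0;
    counts[b]++;
  }
  std::vector<size_t> cum(nbins + 1, 0);
  for (int b = 0; b < nbins; ++b) cum[b + 1] = cum[b] + counts[b];
  std::vector<int> bin_of(ranks.size());
  std::map<int, std::vector<double>> needed;
  for (size_t r = 0; r < ranks.size(); ++r) {
    int b = static_cast<int>(
      std::upper_bound(cum.begin() + 1, cum.end(), ranks[r]) -
      (cum.begin() + 1));
    bin_of[r] = b;
    needed[b]; // create slot
  }
  for (auto& kv : needed) kv.second.reserve(counts[kv.first] + 1);
  for (size_t i = 0; i < n; ++i) {
    int b = static_cast<int>((v[i] - vmin) / width);
    if (b >= nbins) b = nbins - 1;
    if (b < 0) b = 0;
    auto it = needed.find(b);
    if (it != needed.end()) it->second.push_back(v[i]);
  }
  for (auto& kv : needed) std::sort(kv.second.begin(), kv.second.end());
  for (size_t r = 0; r < ranks.size(); ++r) {
    const int b = bin_of[r];
    out[r] = needed[b][ranks[r] - cum[b]];
  }
  return out;
}

// Type-7 quantiles (R default) at probabilities p1 < p2.
static void two_quantiles(const std::vector<double>& v, double p1, double p2,
                          double vmin, double vmax,
                          double& q1, double& q2) {
  const size_t n = v.size();
  const double h1 = (n - 1) * p1, h2 = (n - 1) * p2;
  const size_t k1 = static_cast<size_t>(std::floor(h1));
  const size_t k2 = static_cast<size_t>(std::floor(h2));
  std::vector<size_t> ranks;
  ranks.push_back(k1);
  if (k1 + 1 < n) ranks.push_back(k1 + 1);
  ranks.push_back(k2);
  if (k2 + 1 < n) ranks.push_back(k2 + 1);
  std::vector<double> os = order_stats(v, ranks, vmin, vmax);
  size_t i = 0;
  const double x1lo = os[i++];
  const double x1hi = (k1 + 1 < n) ? os[i++] : x1lo;
  const double x2lo = os[i++];
  const double x2hi = (k2 + 1 < n) ? os[i++] : x2lo;
  q1 = x1lo + (h1 - k1) * (x1hi - x1lo);
  q2 = x2lo + (h2 - k2) * (x2hi - x2lo);
}

// Subsampling percentile null for coherence-modulation maps.
// `stack`: bins x pairs matrix of normalised coherence values.
// Per repetition: draw n_sub columns without replacement (R RNG), split in
// half, subtract the first half from the second member-by-member, and take
// the lo_p and hi_p percentiles over all bins x (n_sub/2) differences.
// [[Rcpp::export]]
List subsample_percentiles_cpp(NumericMatrix stack, int n_sub, int n_rep,
                               double lo_p, double hi_p) {
  const int nb = stack.nrow();
  const int np = stack.ncol();
  const int half = n_sub / 2;
  NumericVector lo(n_rep), hi(n_rep);
  std::vector<double> diffs(static_cast<size_t>(nb) * half);
  for (int r = 0; r < n_rep; ++r) {
    IntegerVector idx = Rcpp::sample(np, n_sub, false); // 1-based
    size_t q = 0;
    double vmin = R_PosInf, vmax = R_NegInf;
    for (int j = 0; j < half; ++j) {
      const double* ctrl = &stack(0, idx[j] - 1);
      const double* drug = &stack(0, idx[half + j] - 1);
      for (int i = 0; i < nb; ++i) {
        const double d = drug[i] - ctrl[i];
        diffs[q++] = d;
        if (d < vmin) vmin = d;
        if (d > vmax) vmax = d;
      }
    }
    two_quantiles(diffs, lo_p, hi_p, vmin, vmax, lo[r], hi[r]);
  }
  return List::create(_["low"] = lo, _["high"] = hi);
}
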