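#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// entropy (nats) of a contiguous-block partition given its breakpoints
// strictly inside (0, L); block sizes are the gaps between 0, breaks..., L
static double partition_entropy(const std::vector<int> &breaks, int L) {
  double acc = 0.0;
  int prev = 0;
  for (size_t i = 0; i <= breaks.size(); ++i) {
    int end = (i == breaks.size()) ? L : breaks[i];
    int d = end - prev;
    if (d > 0) acc += (double)d * std::log((double)d);
    prev = end;
  }
  return std::log((double)L) - acc / (double)L;
}

// circularly shift a genome-wide breakpoint set by delta and clip to the
// window (0, L) (positions strictly inside)
static void shifted_breaks(const IntegerVector &breaks, int delta, int n_bins,
                           int L, std::vector<int> &out) {
  out.clear();
  for (int i = 0; i < breaks.size(); ++i) {
    int p = (breaks[i] + delta) % n_bins;
    if (p > 0 && p < L) out.push_back(p);
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
}

// Null VI draws for windows of a given length: both inputs' genome-wide
// boundary sets are independently circularly shifted and clipped to the
// window. This preserves each input's boundary spacing (hence TAD-length
// multiset) while randomising alignment and window content.
// [[Rcpp::export]]
NumericVector cpp_tadsim_null(int window_len, IntegerVector breaks1,
                              IntegerVector breaks2, int n_bins,
                              int n_draws, bool normalize) {
  NumericVector out(n_draws);
  std::vector<int> b1, b2, joint;
  double logL = std::log((double)window_len);
  for (int d = 0; d < n_draws; ++d) {
    int d1 = (int)(unif_rand() * n_bins); if (d1 >= n_bins) d1 = n_bins - 1;
    int d2 = (int)(unif_rand() * n_bins); if (d2 >= n_bins) d2 = n_bins - 1;
    shifted_breaks(breaks1, d1, n_bins, window_len, b1);
    shifted_breaks(breaks2, d2, n_bins, window_len, b2);
    joint.clear();
    joint.reserve(b1.size() + b2.size());
    std::merge(b1.begin(), b1.end(), b2.begin(), b2.end(),
               std::back_inserter(joint));
    joint.erase(std::unique(joint.begin(), joint.end()), joint.end());
    double vi = 2.0 * partition_entropy(joint, window_len)
              - partition_entropy(b1, window_len)
              - partition_entropy(b2, window_len);
    if (vi < 0) vi = 0;
    out[d] = normalize ? vi / logL : vi;
  }
  return out;
}
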