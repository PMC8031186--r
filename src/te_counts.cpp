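#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// All-pairs delayed transfer entropy and sorted local transfer entropy on a
// binary raster, plug-in estimate over the joint of (i_t, i_{t-1}, j_{t-d}).
//
// Spike bins arrive as 1-based, sorted, deduplicated integer vectors per
// neuron. Targets (rows of the output) come from `target_bins`, sources
// (columns) from `source_bins`; passing the same list twice gives the usual
// within-recording estimate, passing jittered sources against original
// targets gives the surrogate estimate.
//
// Valid time range for delay d (1-based t): t in [max(2, d+1), n_bins], so
// t-1 and t-d always index into the raster. Zero-probability cells of the
// joint contribute zero. Logarithm base 2 (bits).

namespace {

// column-store: for each bin, which neurons spike there
struct BinIndex {
  std::vector<int> ptr;   // size n_bins + 2
  std::vector<int> ids;   // neuron indices, grouped by bin
  BinIndex(const List& bins, int n_bins) {
    int n = bins.size();
    ptr.assign(n_bins + 2, 0);
    long total = 0;
    for (int j = 0; j < n; ++j) total += as<IntegerVector>(bins[j]).size();
    ids.resize(total);
    for (int j = 0; j < n; ++j) {
      IntegerVector b = bins[j];
      for (int k = 0; k < b.size(); ++k) ptr[b[k] + 1]++;
    }
    for (int t = 1; t <= n_bins + 1; ++t) ptr[t] += ptr[t - 1];
    std::vector<int> fill(ptr.begin(), ptr.end());
    for (int j = 0; j < n; ++j) {
      IntegerVector b = bins[j];
      for (int k = 0; k < b.size(); ++k) ids[fill[b[k]]++] = j;
    }
  }
  inline int begin(int t) const { return ptr[t]; }
  inline int end(int t) const { return ptr[t + 1]; }
};

inline int count_in_range(const IntegerVector& b, int lo, int hi) {
  // number of entries in [lo, hi] of a sorted vector
  if (lo > hi) return 0;
  const int* p = b.begin();
  const int* q = b.end();
  return int(std::upper_bound(p, q, hi) - std::lower_bound(p, q, lo));
}

} // namespace

// [[Rcpp::export(name = ".te_slte_all_pairs_cpp")]]
List te_slte_all_pairs_cpp(List target_bins, List source_bins, int n_bins,
                           int d_max) {
  const int n_tgt = target_bins.size();
  const int n_src = source_bins.size();
  if (n_bins < 2) stop("raster too short for transfer entropy");
  const double LOG2 = std::log(2.0);

  BinIndex tgt(target_bins, n_bins);
  BinIndex src(source_bins, n_bins);

  NumericVector te(double(n_tgt) * n_src * (d_max + 1));
  NumericVector slte(double(n_tgt) * n_src * (d_max + 1));

  std::vector<double> N111(size_t(n_tgt) * n_src);
  std::vector<double> N101(size_t(n_tgt) * n_src);
  std::vector<double> N011(size_t(n_tgt) * n_src);
  std::vector<char> inA(n_tgt, 0), inB(n_tgt, 0);

  // per-target consecutive-spike (t-1, t) pair bins: bins t such that both
  // t and t-1 are spikes; precompute once
  std::vector<std::vector<int>> pair_bins(n_tgt);
  for (int i = 0; i < n_tgt; ++i) {
    IntegerVector b = target_bins[i];
    for (int k = 1; k < b.size(); ++k)
      if (b[k] == b[k - 1] + 1) pair_bins[i].push_back(b[k]);
  }

  for (int d = 0; d <= d_max; ++d) {
    const int t0 = std::max(2, d + 1);     // first valid t, 1-based
    const double Tv = double(n_bins - t0 + 1);
    if (Tv < 1) stop("raster shorter than d + 2 bins at delay ", d);

    std::fill(N111.begin(), N111.end(), 0.0);
    std::fill(N101.begin(), N101.end(), 0.0);
    std::fill(N011.begin(), N011.end(), 0.0);

    for (int t = t0; t <= n_bins; ++t) {
      const int sb = src.begin(t - d), se = src.end(t - d);
      if (sb == se) continue;
      const int ab = tgt.begin(t), ae = tgt.end(t);
      const int bb = tgt.begin(t - 1), be = tgt.end(t - 1);
      for (int k = ab; k < ae; ++k) inA[tgt.ids[k]] = 1;
      for (int k = bb; k < be; ++k) inB[tgt.ids[k]] = 1;
      for (int s = sb; s < se; ++s) {
        const size_t off = size_t(src.ids[s]) * n_tgt;
        for (int k = ab; k < ae; ++k) {
          const int i = tgt.ids[k];
          if (inB[i]) N111[off + i] += 1.0; else N101[off + i] += 1.0;
        }
        for (int k = bb; k < be; ++k) {
          const int i = tgt.ids[k];
          if (!inA[i]) N011[off + i] += 1.0;
        }
      }
      for (int k = ab; k < ae; ++k) inA[tgt.ids[k]] = 0;
      for (int k = bb; k < be; ++k) inB[tgt.ids[k]] = 0;
    }

    // per-target (a,b) marginals over the valid range
    std::vector<double> C11(n_tgt), C10(n_tgt), C01(n_tgt);
    for (int i = 0; i < n_tgt; ++i) {
      IntegerVector b = target_bins[i];
      double c1dot = count_in_range(b, t0, n_bins);        // i_t = 1
      double cdot1 = count_in_range(b, t0 - 1, n_bins - 1); // i_{t-1} = 1
      double c11 = 0;
      for (size_t k = 0; k < pair_bins[i].size(); ++k)
        if (pair_bins[i][k] >= t0) c11 += 1.0;
      C11[i] = c11;
      C10[i] = c1dot - c11;
      C01[i] = cdot1 - c11;
    }
    // per-source c-marginal
    std::vector<double> S1(n_src);
    for (int j = 0; j < n_src; ++j) {
      IntegerVector b = source_bins[j];
      S1[j] = count_in_range(b, t0 - d, n_bins - d);
    }

    const size_t d_off = size_t(d) * n_tgt * n_src;
    for (int j = 0; j < n_src; ++j) {
      const size_t off = size_t(j) * n_tgt;
      for (int i = 0; i < n_tgt; ++i) {
        double N[2][2][2]; // [a][b][c]
        N[1][1][1] = N111[off + i];
        N[1][0][1] = N101[off + i];
        N[0][1][1] = N011[off + i];
        N[0][0][1] = S1[j] - N[1][1][1] - N[1][0][1] - N[0][1][1];
        N[1][1][0] = C11[i] - N[1][1][1];
        N[1][0][0] = C10[i] - N[1][0][1];
        N[0][1][0] = C01[i] - N[0][1][1];
        N[0][0][0] = Tv - N[1][1][1] - N[1][0][1] - N[0][1][1] - N[0][0][1]
                        - N[1][1][0] - N[1][0][0] - N[0][1][0];
        const double Nb[2] = { C10[i] + (Tv - C11[i] - C10[i] - C01[i]),
                               C11[i] + C01[i] }; // N(.,b,.)
        double te_ij = 0.0, slte_ij = 0.0;
        for (int a = 0; a < 2; ++a) {
          const double Nab0 = N[a][0][0] + N[a][0][1];
          const double Nab1 = N[a][1][0] + N[a][1][1];
          for (int b = 0; b < 2; ++b) {
            const double Nabdot = (b == 0) ? Nab0 : Nab1;
            for (int c = 0; c < 2; ++c) {
              const double nabc = N[a][b][c];
              if (nabc <= 0.0) continue;
              const double Ndbc = N[0][b][c] + N[1][b][c];
              // log( p(a|b,c) / p(a|b) )
              const double local =
                std::log((nabc / Ndbc) / (Nabdot / Nb[b])) / LOG2;
              const double p = nabc / Tv;
              te_ij += p * local;
              slte_ij += ((a == c) ? 1.0 : -1.0) * p * local;
            }
          }
        }
        te[d_off + size_t(j) * n_tgt + i] = te_ij;
        slte[d_off + size_t(j) * n_tgt + i] = slte_ij;
      }
    }
  }

  IntegerVector dims = IntegerVector::create(n_tgt, n_src, d_max + 1);
  te.attr("dim") = dims;
  slte.attr("dim") = dims;
  return List::create(_["te"] = te, _["slte"] = slte);
}
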