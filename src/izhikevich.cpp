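#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Current-based Izhikevich network integrated at 1 ms (two 0.5 ms substeps
// for the voltage equation, the standard scheme for this model). Spikes are
// delivered along edges after integer conduction delays; each neuron gets an
// independent Gaussian noise current per step (scaled by noise_exc /
// noise_inh for regular-spiking vs fast-spiking cells). Uses R's RNG so runs
// are reproducible from set.seed().
//
// pre / post / weight / delay describe edges (0-based neuron indices,
// delay >= 1 ms). A spike fired at step t (0-based) is reported as occurring
// in bin t and reaches each target at step t + delay.

// [[Rcpp::export(name = ".izhikevich_sim_cpp")]]
List izhikevich_sim_cpp(NumericVector a, NumericVector b, NumericVector c,
                        NumericVector d, IntegerVector pre, IntegerVector post,
                        NumericVector weight, IntegerVector delay,
                        int n_steps, NumericVector noise_sd) {
  const int n = a.size();
  const int m = pre.size();
  int max_delay = 1;
  for (int e = 0; e < m; ++e) max_delay = std::max(max_delay, delay[e]);

  // adjacency by presynaptic neuron
  std::vector<int> eptr(n + 1, 0);
  for (int e = 0; e < m; ++e) eptr[pre[e] + 1]++;
  for (int j = 1; j <= n; ++j) eptr[j] += eptr[j - 1];
  std::vector<int> etgt(m), edel(m);
  std::vector<double> ew(m);
  {
    std::vector<int> fill(eptr.begin(), eptr.end());
    for (int e = 0; e < m; ++e) {
      int k = fill[pre[e]]++;
      etgt[k] = post[e]; ew[k] = weight[e]; edel[k] = delay[e];
    }
  }

  std::vector<double> v(n, -65.0), u(n);
  for (int i = 0; i < n; ++i) u[i] = b[i] * v[i];

  const int L = max_delay + 1;
  std::vector<std::vector<double>> buf(L, std::vector<double>(n, 0.0));
  std::vector<std::vector<int>> spikes(n);
  std::vector<int> fired;
  fired.reserve(n);

  RNGScope scope;
  for (int t = 0; t < n_steps; ++t) {
    const int slot = t % L;
    std::vector<double>& I = buf[slot];

    fired.clear();
    for (int i = 0; i < n; ++i) {
      if (v[i] >= 30.0) {
        fired.push_back(i);
        spikes[i].push_back(t);
        v[i] = c[i];
        u[i] += d[i];
      }
    }
    for (size_t f = 0; f < fired.size(); ++f) {
      const int j = fired[f];
      for (int k = eptr[j]; k < eptr[j + 1]; ++k)
        buf[(t + edel[k]) % L][etgt[k]] += ew[k];
    }
    for (int i = 0; i < n; ++i) {
      const double Ii = I[i] + noise_sd[i] * norm_rand();
      double vi = v[i], ui = u[i];
      vi += 0.5 * (0.04 * vi * vi + 5.0 * vi + 140.0 - ui + Ii);
      if (vi < -90.0) vi = -90.0;  // inhibitory reversal floor: no rebound
      vi += 0.5 * (0.04 * vi * vi + 5.0 * vi + 140.0 - ui + Ii);
      if (vi < -90.0) vi = -90.0;
      ui += a[i] * (b[i] * vi - ui);
      if (!R_finite(vi)) vi = 30.0; // numerical guard: clamp runaway to peak
      v[i] = vi; u[i] = ui;
    }
    std::fill(I.begin(), I.end(), 0.0);
  }

  List out(n);
  for (int i = 0; i < n; ++i) out[i] = wrap(spikes[i]);
  return out;
}

// Jitter surrogate for one neuron's spike train: each spike, in temporal
// order, moves uniformly at random to one of the currently silent bins
// within +/- window of its original bin (the original bin itself excluded);
// if no silent bin exists in the window the spike stays. Spike count is
// always preserved. `bins` are 1-based sorted spike bins, n_bins the raster
// length. Uses R's RNG.

// [[Rcpp::export(name = ".jitter_spikes_cpp")]]
IntegerVector jitter_spikes_cpp(IntegerVector bins, int n_bins, int window) {
  const int ns = bins.size();
  std::vector<char> occ(n_bins + 1, 0);
  for (int k = 0; k < ns; ++k) occ[bins[k]] = 1;
  IntegerVector out(ns);
  std::vector<int> cand;
  cand.reserve(2 * window + 1);
  RNGScope scope;
  for (int k = 0; k < ns; ++k) {
    const int b = bins[k];
    cand.clear();
    const int lo = std::max(1, b - window), hi = std::min(n_bins, b + window);
    for (int t = lo; t <= hi; ++t)
      if (t != b && !occ[t]) cand.push_back(t);
    if (cand.empty()) {
      out[k] = b;
    } else {
      const int pick = cand[int(unif_rand() * cand.size()) % cand.size()];
      occ[b] = 0;
      occ[pick] = 1;
      out[k] = pick;
    }
  }
  return out;
}
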