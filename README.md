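# spikeTE

Effective connectivity, excitatory/inhibitory cell typing, and network
controllability analysis for millisecond-resolution neuronal spike trains.

## What it does, and for whom

Multi-electrode array recordings of cortical tissue yield spike trains from
hundreds of sorted units, but not the circuit: who drives whom, with what
sign, and which neurons sit in topologically influential positions. spikeTE
is for systems neuroscientists who want to go from a spike table to a
signed, directed effective network and its graph-theoretic readout:

- **Connectivity** — delayed transfer entropy per ordered pair,

  $$TE_{J\to I}(d) = \sum_{i_t,\,i_{t-1},\,j_{t-d}} p(i_t,i_{t-1},j_{t-d})
  \log_2\frac{p(i_t\mid i_{t-1},j_{t-d})}{p(i_t\mid i_{t-1})},$$

  scanned over conduction delays $d = 0\ldots30$ ms. Each pair is
  summarized by Strength (peak TE) and Sharpness (fraction of TE mass up to
  $\tau = 4$ ms after the peak). Connections are accepted against a
  spike-jitter surrogate null: spikes relocated into silent bins within
  ±10 ms, 100 surrogates, and a per-pixel rejection threshold
  $RT = N_{jitt}/(N_{real}+N_{jitt})$ on a 25×25 (Strength, Sharpness)
  grid, accepting pixels with $RT \le 0.34$ — separately for the E→E, E→I,
  I→E, I→I categories. Edge weights are the bias-adjusted strength
  $TE^{real}_{peak}-\overline{TE^{shuffle}_{peak}}$.

- **Cell typing** — sorted local transfer entropy (SLTE) weights each local
  TE term by $(-1)^{(i_t - j_{t-d})}$, making excitatory influence positive
  and inhibitory influence negative. Per neuron, the SLTE values of its
  output pairs (ranked by rate-normalized TE, weakest 10% dropped) are
  summed and clustered together with log firing rate (Ward, 2 clusters);
  the positive-sum cluster is excitatory, per Dale's principle.

- **Topology & control** — k-core centrality by recursive peeling,
  log-normality tests (Anderson–Darling) for rates and weights, the
  13-class directed triad census with independent-dyad expectations, and
  exact minimum feedback vertex sets (MFVS) with critical / intermittent /
  redundant node classification — the node sets whose control can steer
  the whole circuit into stable attractors.

- **Layers** — conversion of a 1D cell-density profile into the five
  laminar boundaries via the three-convex/two-concave landmark rule, and
  depth-based layer labels per neuron.

- **Ground truth** — a seeded Izhikevich-type network simulator
  (log-normal synaptic weights, Dale-consistent signs, 1–10 ms delays)
  whose known connectivity and cell types validate every stage.

## Worked example

Simulate a small circuit with known ground truth and run the full pipeline
(this exact code produced the output below):

```r
library(spikeTE)
sim <- simulateIzhikevich(16, 4, pConnect = 0.15, durationMs = 300000,
                          seed = 2)
cfg <- pipelineConfig(nSurrogates = 20, seed = 2, solverTimeLimit = 30,
                      classifyFvs = TRUE)
bundle <- runPipeline(sim$spikes, cfg)
makeReport(bundle, truth = trueTypes(sim$truth))
```

```
Neurons: 20 (E 16, I 4, unlabeled 0); inhibitory fraction 0.200
Edges accepted: 39 (density 0.1026)
Firing rates: log-normal AD = 2.295, p = 4.7e-06 (mu 2.31, sigma 0.26)
Strengths: log-normal AD = 1.275, p = 0.00215
Mean k-core (E): 2.250
Mean k-core (I): 3.000
MFVS size: 3
FVS ratio E: 0.062, I: 0.500
FVS in max k-core: 100.0% of FVS, 25.0% of max core
E/I accuracy vs truth: E 100.0%, I 100.0%, overall 100.0%
```

Reading it: all 20 neurons were typed correctly from spikes alone; 39 of
380 ordered pairs passed the surrogate test (density 0.10, matching the
generative connection probability 0.15 times the detection recall at this
short duration); and the four inhibitory cells are disproportionately
influential — higher mean coreness (3.00 vs 2.25) and a far higher share of
them in the minimum feedback vertex set (0.50 vs 0.06), the package's core
scientific readout. At this tiny scale the Anderson–Darling test rejects
log-normality of rates; log-normal fits are meaningful at the hundreds-of-
neurons scale. Individual stages are available as plain functions
(`teAllPairs()`, `pairStats()`, `classifyEI()`, `mfvs()`,
`layerBoundaries()`, ...) and the network exports to GraphML or a signed
adjacency CSV via `writeNetwork()`.

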