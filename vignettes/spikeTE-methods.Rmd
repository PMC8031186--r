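---
title: "spikeTE: effective connectivity, cell typing, and controllability from spike trains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spikeTE methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikeTE)
```

## The problem

Cortical microcircuits balance a large excitatory majority against a small
inhibitory minority. Modern multi-electrode recordings deliver spike trains
from hundreds to a thousand sorted units at millisecond resolution, but the
spike trains alone do not say which neurons drive which, which cells are
inhibitory, or which neurons occupy the topologically influential positions.
spikeTE implements a complete analysis chain for these questions:

1. **Effective connectivity** between every ordered neuron pair from delayed
   transfer entropy, with a jitter-surrogate null deciding which pairs are
   genuine connections.
2. **Excitatory/inhibitory cell typing** from the sign structure of sorted
   local transfer entropy, via two-cluster Ward agglomeration.
3. **Topological influence** of each neuron: degree statistics, k-core
   centrality, triad-motif enrichment, and minimum feedback vertex set
   (MFVS) controllability.
4. **Laminar context**: a rule-based conversion of a 1D cell-density profile
   into five cortical layer boundaries.

A seeded Izhikevich-type network simulator with known signed connectivity
provides ground truth for validating every stage.

## Delayed transfer entropy and pair summaries

For binary spike indicators $i_t$ (target) and $j_t$ (source) at 1 ms bins,
the delayed transfer entropy is the plug-in estimate

$$TE_{J\to I}(d) \;=\; \sum_{i_t,\,i_{t-1},\,j_{t-d}}
p(i_t, i_{t-1}, j_{t-d})\,
\log_2\frac{p(i_t \mid i_{t-1}, j_{t-d})}{p(i_t \mid i_{t-1})}.$$

Only the most recent own-history bin and a single source bin at lag $d$
enter the conditioning; higher-order embeddings change the resulting
networks very little at these timescales while multiplying the state space.
Sums run over $t = \max(1, d) \dots n_{\text{bins}}-1$ (all three indices in
range, no padding); empty cells of the empirical joint contribute zero, so
the estimate is always finite and non-negative. All outputs are in bits.

Scanning $d = 0 \dots 30$ ms (the conduction-delay window for slice-scale
distances) yields a delay profile per ordered pair, summarized by

* **Strength** — the peak of $TE(d)$;
* **Sharpness** — $\sum_{d=0}^{d_{peak}+\tau} TE(d) \big/ \sum_{d=0}^{30}
  TE(d)$ with $\tau = 4$ ms. A direct synaptic connection concentrates its
  TE mass in a narrow band after the peak, so sharp profiles score near 1.
  The numerator starts at $d = 0$ as the definition is written; a
  peak-centered window (the older "coincidence index" convention) is
  available via `sharpness(..., peakCentered = TRUE)` but is not the
  default. Identically zero profiles get sharpness 0 and are never
  selectable as connections.

Two per-pair quantities support cell typing:

* **Normalized TE** $TE_{nor} = TE_{peak} / \lvert p\log_2 p + (1-p)\log_2
  (1-p)\rvert$, where $p$ is the *target* neuron's per-bin spike
  probability. The absolute value makes larger mean stronger; $p$ is capped
  below at $1/n_{\text{bins}}$ so the normalization stays finite.
* **E-I bias** — the sorted local transfer entropy at the TE peak delay.
  SLTE weights each local TE term by $(-1)^{(i_t - j_{t-d})}$: $+1$ when
  target and delayed source show the same event, $-1$ otherwise. Excitatory
  coupling (source spike makes a target spike more likely) accumulates
  positive terms; inhibitory coupling (source spike silences an otherwise
  active target) accumulates negative ones.

The all-pairs kernel (`teAllPairs()`) is a single C++ pass over the sparse
raster per delay; it is tested to $10^{-12}$ against a naive histogram
implementation, and the per-pair functions are exact slices of it.

## Connection selection: jitter surrogates and the rejection map

Each surrogate relocates every presynaptic spike, uniformly at random, to a
currently silent bin within $\pm 10$ ms (the original bin excluded; a spike
with no silent neighbor stays put). Spike counts — hence rates — are exactly
preserved while millisecond timing is destroyed. One hundred surrogates are
the default; desk-scale analyses may reduce this via configuration, and the
count is recorded with the results.

Real and surrogate (Strength, Sharpness) points are pooled on a
$25 \times 25$ pixel grid (Strength on $\log_{10}$, because strengths are
log-normally distributed; Sharpness linear; bounds = pooled range with 1%
padding). Each pixel gets a rejection threshold

$$RT = \frac{N_{jitt}}{N_{real} + N_{jitt}},$$

and a pair is accepted as connected when its pixel's $RT \le 0.34$. Pixels
containing no points are undefined and treated as rejecting — a conservative
convention. Selection is performed **separately for the four connection
categories** (E→E, E→I, I→E, I→I), which is why cell typing must precede
connection determination. Accepted edges carry the bias-adjusted strength
$IT_{j \to i} = TE^{real}_{peak} - \overline{TE^{shuffle}_{peak}}$ as weight
and the presynaptic label's sign.

## E/I classification

Per presynaptic neuron, output pairs are ranked by normalized TE and the
weakest 10% discarded (retained count $\lfloor 0.9\,n_{out}\rfloor$, at
least 1), trimming estimation noise while keeping nearly all evidence. The
sum of the surviving E-I biases forms the first feature; $\log_{10}$ firing
rate the second. Features are z-scored per axis — any affine rescaling of
either axis is then immaterial — and Ward variance-minimization clustering
(`hclust(method = "ward.D2")`) is cut at two clusters. The cluster with the
larger mean SLTE sum is excitatory, per Dale's principle; neurons with no
output candidates are reported as unlabeled rather than guessed.

## Topology and controllability

* **Coreness** uses the undirected simple projection with total degree
  (configurable to in/out): recursive peeling of nodes with degree below k.
* **Log-normality** of rates and strengths is tested by the
  Anderson–Darling normality test on the log sample (estimated-parameter
  critical values, via the nortest package).
* **Triad motifs** are counted into the standard 13 connected directed
  classes (021D ... 300; the adjacency-pattern table is documented at
  `triadMotifCensus()`); expected counts come from treating the three dyads
  of a triple as independent draws from the empirical dyad distribution
  (null/asymmetric/reciprocal), enumerated over all 64 dyad-state
  assignments.
* **MFVS**: a feedback vertex set is a node set whose incoming-edge removal
  leaves the graph acyclic; controlling it can steer the network into
  steady or periodic attractors. The solver here is exact branch and bound:
  self-looped nodes are forced in; acyclic tails are trimmed; nodes with a
  unique predecessor or successor are contracted into it (these reductions
  preserve the optimum); branching follows a shortest cycle found by BFS;
  and a greedy vertex-disjoint cycle packing provides the lower bound. If
  the time budget expires before optimality is proven the result is
  reported `"unsolved"` — never a heuristic answer. Node classes (critical
  = in every MFVS, intermittent = in some, redundant = in none) are decided
  by two exact re-solves per cycle node, exactly as one would with an ILP
  solver by forcing indicator variables. Everything is verified against
  exhaustive subset enumeration on small digraphs in the test suite.

## Layer boundaries from a density profile

The 1D cell-density histogram along the depth axis shows three convex
points (centers of L3, L4, and a deep-L6 peak) and two concave points
between them. After moving-average smoothing (default window 5% of the
profile length), the three most prominent maxima and the interleaved minima
are located; fewer than three maxima raises an explicit classed error. The
boundaries are then: L1|L2/3 at one third of the surface-to-first-peak
distance (reading "1/3 from the surface" as a fraction of that interval);
L2/3|L4 at the first minimum; L4|L5 midway between second maximum and
second minimum; L5|L6 midway between second minimum and third maximum.
Depth labels use half-open intervals, surface = 0.

This module expects an already-extracted 1D profile (or the synthetic
generator's); image processing, staining and registration are outside the
package's scope.

## The synthetic generator and its calibration

`simulateIzhikevich()` is the ground-truth source for every recovery claim.
Design choices, fixed once:

* Canonical regular-spiking / fast-spiking parameterizations with per-cell
  heterogeneity ($r$ uniform), integrated at 1 ms in two half-steps —
  aligning simulation and analysis bins.
* Current-based synapses with log-normal weight magnitudes
  (`sdlogW = 0.5`), signs by Dale's principle, integer conduction delays
  uniform on 1–10 ms. Defaults: median excitatory weight 3, median
  inhibitory weight 90 (mV-equivalent current), noise s.d. 7 mV
  (excitatory) / 5.6 mV (inhibitory) per step, i.e. `noiseScale = 1.4`.
  These were calibrated once so the network sits in a sparse asynchronous
  regime — excitatory cells near 9–10 Hz, inhibitory cells near 16–17 Hz,
  every neuron active — and then frozen. Strong inhibition is needed
  because a suppression of an already-sparse target carries intrinsically
  less information per event than an excitatory coincidence; weak
  inhibitory weights leave the SLTE sums of inhibitory cells indistinct
  from noise.
* The membrane is floored at $-90$ mV (an inhibitory-reversal-like bound).
  Without it, very strong inhibitory inputs push the quadratic voltage
  equation into a regime where it rebounds into spiking, which converts
  inhibitory connections into apparent excitation — an artifact of the
  polynomial model, not a physiological effect.
* Inhibitory spike-timing-dependent plasticity is not implemented: the
  validation regime reaches its target behavior with static weights, and a
  plasticity rule would make ground truth time-dependent.

What the generator does *not* emulate: bursting cell classes, conductance
synapses, distance-dependent connectivity, common slow drives, or
electrode-level artifacts (spike sorting errors, near-electrode bias).
Passing recovery tests on these simulations therefore demonstrates the
correctness and calibration of the estimation chain, not its robustness to
every pathology of real MEA data.

## Problem sizes and numerical conventions

The validation suite runs five seeded 80E/20I networks for 60 simulated
minutes each for the classification claims; connection-recovery checks use
a 30-minute network with 20 surrogates, and the null calibration a
50-neuron connectionless network (10 minutes, 20 surrogates). Combinatorial
oracles (exhaustive MFVS, peeling coreness, triple-enumeration motifs) run
on hundreds of random graphs with up to 8–25 nodes. Ties in the TE delay
profile resolve to the earliest delay; multiple spikes in one bin collapse
to a single 1; duration defaults to the smallest whole millisecond
strictly greater than the last spike when unspecified.

## Known limitations

* The plug-in TE estimator is biased upward at short recordings; the bias
  is handled by the surrogate subtraction for weights and by recording
  length for classification, not by analytic correction.
* Rejection-map axes bounds are data-dependent (pooled range), so RT values
  are comparable within one dataset and category, not across datasets.
* MFVS is NP-hard; dense networks of several hundred nodes may exhaust the
  time budget, yielding an explicit `"unsolved"` status.
* Neurons with no output candidates cannot be typed by the SLTE rule and
  are reported unlabeled.
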