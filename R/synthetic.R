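#' Simulate an Izhikevich-type spiking network with known connectivity
#'
#' Generates a random signed, delayed synaptic graph obeying Dale's principle
#' and integrates the canonical two-variable quadratic integrate-and-fire
#' dynamics at 1 ms resolution with independent Gaussian noise drive per
#' neuron. Excitatory cells use the regular-spiking parameterization
#' (a = 0.02, b = 0.2, c = -65 + 15 r^2, d = 8 - 6 r^2) and inhibitory cells
#' the fast-spiking one (a = 0.02 + 0.08 r, b = 0.25 - 0.05 r, c = -65,
#' d = 2), with r uniform per neuron. Synapses are current-based with
#' log-normal weight magnitudes; spikes are delivered after integer
#' conduction delays drawn uniformly from `delayRangeMs`.
#'
#' The default weight and noise scales were calibrated once so that the
#' network is in a sparse asynchronous regime (population rates of a few Hz,
#' inhibitory cells faster than excitatory ones) and then frozen; see the
#' methods vignette.
#'
#' @param nExc,nInh numbers of excitatory and inhibitory neurons (>= 1)
#' @param pConnect connection probability per ordered pair (0 < p <= 1; 0 is
#'   allowed and yields a noise-only network for null calibration)
#' @param delayRangeMs integer range (min, max) of conduction delays, ms
#' @param durationMs recording length in ms
#' @param noiseScale multiplier on the per-step noise current s.d.
#'   (5 mV for excitatory, 4 mV for inhibitory at scale 1)
#' @param seed RNG seed; the full run is reproducible from it
#' @param wExc,wInh median synaptic weight magnitude (mV-equivalent current)
#'   for excitatory and inhibitory connections
#' @param sdlogW log-space s.d. of the log-normal weight magnitudes
#' @return list with `spikes` (a [SpikeTrainSet-class] whose metadata carries
#'   `true_type`) and `truth` (a [GroundTruthNetwork-class])
#' @export
simulateIzhikevich <- function(nExc, nInh, pConnect = 0.1,
                               delayRangeMs = c(1, 10), durationMs = 60000,
                               noiseScale = 1.4, seed = 1,
                               wExc = 3, wInh = 90, sdlogW = 0.5) {
  if (nExc < 1 || nInh < 1) stop("need at least one neuron of each type")
  if (pConnect < 0 || pConnect > 1) stop("pConnect must be in [0, 1]")
  if (durationMs <= 0) stop("durationMs must be positive")
  set.seed(seed)
  n <- nExc + nInh
  types <- c(rep("E", nExc), rep("I", nInh))
  ids <- sprintf("n%03d", seq_len(n))

  A <- matrix(0, n, n)       # A[target, source]
  D <- matrix(0L, n, n)
  if (pConnect > 0) {
    conn <- matrix(stats::runif(n * n) < pConnect, n, n)
    diag(conn) <- FALSE
    m <- sum(conn)
    mag <- stats::rlnorm(m, meanlog = 0, sdlog = sdlogW)
    src <- col(conn)[conn]
    w <- ifelse(types[src] == "E", wExc, -wInh) * mag
    A[conn] <- w
    D[conn] <- sample(delayRangeMs[1]:delayRangeMs[2], m, replace = TRUE)
  }
  truth <- methods::new("GroundTruthNetwork", adjacency = A, delays = D,
                        types = types, neuronIds = ids)

  r <- stats::runif(n)
  a <- ifelse(types == "E", 0.02, 0.02 + 0.08 * r)
  b <- ifelse(types == "E", 0.2, 0.25 - 0.05 * r)
  cc <- ifelse(types == "E", -65 + 15 * r^2, -65)
  d <- ifelse(types == "E", 8 - 6 * r^2, 2)
  noise <- ifelse(types == "E", 5, 4) * noiseScale

  edges <- which(A != 0, arr.ind = TRUE)
  sp <- .izhikevich_sim_cpp(a, b, cc, d,
                            pre = as.integer(edges[, 2] - 1L),
                            post = as.integer(edges[, 1] - 1L),
                            weight = A[edges], delay = as.integer(D[edges]),
                            n_steps = as.integer(durationMs),
                            noise_sd = noise)
  spikes <- lapply(sp, function(s) as.numeric(s) + 0.5) # center of the ms bin
  meta <- data.frame(true_type = types, stringsAsFactors = FALSE)
  sts <- SpikeTrainSet(spikes, ids, durationMs = durationMs, metadata = meta)
  list(spikes = sts, truth = truth)
}

#' Random simple directed graph
#'
#' Each unordered node pair is connected with probability `pEdge`; a
#' connected pair is reciprocal with probability `pBidir`, otherwise a single
#' direction is chosen uniformly. No self-loops. Used as a combinatorial
#' oracle fixture for the k-core, motif and feedback-vertex-set routines.
#'
#' @param n number of nodes
#' @param pEdge probability a pair is connected
#' @param pBidir probability a connected pair is bidirectional
#' @param seed RNG seed
#' @return an [EffectiveNetwork-class] (unsigned, unlabeled)
#' @export
randomDirectedGraph <- function(n, pEdge, pBidir = 0, seed = 1) {
  if (n < 1) stop("n must be >= 1")
  if (pEdge < 0 || pEdge > 1 || pBidir < 0 || pBidir > 1)
    stop("probabilities must be in [0, 1]")
  set.seed(seed)
  ids <- paste0("v", seq_len(n))
  from <- character(0); to <- character(0)
  if (n >= 2) {
    pairs <- utils::combn(n, 2)
    on <- stats::runif(ncol(pairs)) < pEdge
    for (k in which(on)) {
      u <- ids[pairs[1, k]]; v <- ids[pairs[2, k]]
      if (stats::runif(1) < pBidir) {
        from <- c(from, u, v); to <- c(to, v, u)
      } else if (stats::runif(1) < 0.5) {
        from <- c(from, u); to <- c(to, v)
      } else {
        from <- c(from, v); to <- c(to, u)
      }
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = TRUE, vertices = data.frame(name = ids))
  methods::new("EffectiveNetwork", graph = g)
}

#' Synthetic 1D cortical cell-density profile
#'
#' Sum of Gaussian bumps on the normalized depth axis `[0, 1]` (0 = pial
#' surface, 1 = white matter) with optional additive Gaussian noise; the
#' fixture for layer-boundary detection. The layer rule expects exactly three
#' density peaks; other counts are flagged with a warning but still returned.
#'
#' @param peaks list of `c(depth, amplitude, width)` triples with strictly
#'   increasing depths in (0, 1)
#' @param nPoints number of depth samples
#' @param noiseSd s.d. of additive noise (same units as amplitude)
#' @param seed RNG seed for the noise
#' @return `data.frame` with columns `depth` and `density`
#' @export
syntheticDensityProfile <- function(peaks, nPoints = 200, noiseSd = 0,
                                    seed = 1) {
  depths <- vapply(peaks, `[`, numeric(1), 1)
  if (is.unsorted(depths, strictly = TRUE) || any(depths <= 0 | depths >= 1))
    stop("peak depths must be strictly increasing in (0, 1)")
  if (length(peaks) != 3)
    warning("layer-boundary rule expects exactly 3 peaks; got ",
            length(peaks))
  x <- seq(0, 1, length.out = nPoints)
  y <- rep(0, nPoints)
  for (p in peaks) y <- y + p[2] * exp(-(x - p[1])^2 / (2 * p[3]^2))
  if (noiseSd > 0) {
    set.seed(seed)
    y <- y + stats::rnorm(nPoints, sd = noiseSd)
  }
  data.frame(depth = x, density = pmax(y, 0))
}
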