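#' @import methods
#' @importFrom Matrix sparseMatrix
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' Spike-train collection
#'
#' Per-neuron spike times (ms) for one recording, with the recording duration
#' and optional per-neuron metadata (cortical depth, ground-truth cell type,
#' layer). The event-level container from which all binned analyses start.
#'
#' @slot spikes list of sorted numeric vectors, one per neuron, times in ms.
#' @slot neuronIds character vector of unique neuron identifiers.
#' @slot durationMs recording length in ms; all times lie in `[0, durationMs)`.
#' @slot metadata optional `data.frame` with one row per neuron (columns such
#'   as `depth_um`, `true_type`, `layer`), or `NULL`.
#' @export
setClass("SpikeTrainSet",
  representation(spikes = "list", neuronIds = "character",
                 durationMs = "numeric", metadata = "data.frameOrNULL"),
  prototype(spikes = list(), neuronIds = character(0), durationMs = 0,
            metadata = NULL))

setValidity("SpikeTrainSet", function(object) {
  msg <- character(0)
  if (length(object@spikes) != length(object@neuronIds))
    msg <- c(msg, "spikes and neuronIds lengths differ")
  if (anyDuplicated(object@neuronIds))
    msg <- c(msg, "neuron ids must be unique")
  if (length(object@durationMs) != 1 || is.na(object@durationMs) ||
      object@durationMs < 0)
    msg <- c(msg, "durationMs must be a single non-negative number")
  for (k in seq_along(object@spikes)) {
    s <- object@spikes[[k]]
    if (length(s)) {
      if (is.unsorted(s, strictly = FALSE))
        msg <- c(msg, sprintf("spike times of neuron %s are not sorted",
                              object@neuronIds[k]))
      if (min(s) < 0 || max(s) >= object@durationMs)
        msg <- c(msg, sprintf("spike times of neuron %s outside [0, duration)",
                              object@neuronIds[k]))
    }
  }
  if (!is.null(object@metadata) &&
      nrow(object@metadata) != length(object@neuronIds))
    msg <- c(msg, "metadata must have one row per neuron")
  if (length(msg)) msg else TRUE
})

#' Binary binned raster
#'
#' Binary neurons-by-time-bins matrix at a fixed bin width (default 1 ms); a
#' bin holds 1 when the neuron spiked at least once inside it. The substrate
#' of all transfer-entropy estimation.
#'
#' @slot mat sparse binary matrix (`Matrix::dgCMatrix`), neurons in rows.
#' @slot binMs bin width in ms.
#' @slot neuronIds row identifiers, same ordering as the source spike set.
#' @export
setClass("BinnedRaster",
  representation(mat = "ANY", binMs = "numeric", neuronIds = "character"))

setValidity("BinnedRaster", function(object) {
  msg <- character(0)
  if (!methods::is(object@mat, "sparseMatrix"))
    msg <- c(msg, "mat must be a sparse Matrix")
  else {
    if (nrow(object@mat) != length(object@neuronIds))
      msg <- c(msg, "row count must equal number of neuron ids")
    x <- object@mat@x
    if (length(x) && !all(x == 1))
      msg <- c(msg, "raster entries must be exactly 0 or 1")
  }
  if (object@binMs <= 0) msg <- c(msg, "binMs must be positive")
  if (length(msg)) msg else TRUE
})

#' Ground-truth simulated network
#'
#' Signed adjacency, integer conduction delays and true excitatory/inhibitory
#' cell types of a simulated network; serves as the recovery oracle for the
#' inference pipeline. Outgoing weights of an excitatory neuron are
#' non-negative and of an inhibitory neuron non-positive (Dale's principle);
#' no self-connections; delays of existing connections are at least 1 ms.
#'
#' @slot adjacency numeric matrix, `adjacency[i, j]` the signed weight of the
#'   connection from neuron j onto neuron i (0 = absent).
#' @slot delays integer matrix (ms), aligned with `adjacency`.
#' @slot types character vector, "E" or "I" per neuron.
#' @slot neuronIds neuron identifiers.
#' @export
setClass("GroundTruthNetwork",
  representation(adjacency = "matrix", delays = "matrix",
                 types = "character", neuronIds = "character"))

setValidity("GroundTruthNetwork", function(object) {
  msg <- character(0)
  n <- length(object@neuronIds)
  A <- object@adjacency
  if (!all(dim(A) == c(n, n)) || !all(dim(object@delays) == c(n, n)))
    msg <- c(msg, "adjacency and delays must be n x n")
  if (length(object@types) != n || !all(object@types %in% c("E", "I")))
    msg <- c(msg, "types must be 'E'/'I' per neuron")
  else if (all(dim(A) == c(n, n))) {
    if (any(diag(A) != 0)) msg <- c(msg, "self-connections are not allowed")
    for (j in seq_len(n)) {
      w <- A[, j]
      if (object@types[j] == "E" && any(w < 0))
        msg <- c(msg, "excitatory neuron with negative outgoing weight")
      if (object@types[j] == "I" && any(w > 0))
        msg <- c(msg, "inhibitory neuron with positive outgoing weight")
    }
    if (any(object@delays[A != 0] < 1))
      msg <- c(msg, "delays of existing connections must be >= 1 ms")
  }
  if (length(msg)) msg else TRUE
})

#' Transfer-entropy delay profile for one ordered pair
#'
#' TE(d) and SLTE(d) over delays d = 0..d_max for one ordered (source,
#' target) pair, together with the peak summaries: Strength (peak TE), peak
#' delay, Sharpness (fraction of TE(d) mass up to shortly after the peak),
#' E-I bias (SLTE at the peak delay) and the firing-rate-normalized peak TE.
#'
#' @slot source,target neuron ids.
#' @slot te,slte numeric vectors over delays 0..d_max (bits).
#' @slot peakTe,peakDelay,sharpness,eiBias,teNor scalar summaries.
#' @export
setClass("TEDelayProfile",
  representation(source = "character", target = "character",
                 te = "numeric", slte = "numeric", peakTe = "numeric",
                 peakDelay = "integer", sharpness = "numeric",
                 eiBias = "numeric", teNor = "numeric"))

#' All-pairs transfer-entropy profiles
#'
#' Dense container of TE(d) and SLTE(d) for every ordered neuron pair of a
#' raster: 3-d arrays indexed (target, source, delay + 1). Produced by
#' [teAllPairs()]; per-pair summaries via [pairStats()] and single-pair
#' profiles via [teProfileFromSet()].
#'
#' @slot te,slte numeric arrays `(n, n, dMax + 1)`; `te[i, j, d + 1]` is
#'   TE from neuron j to neuron i at delay d.
#' @slot neuronIds neuron identifiers (both array margins).
#' @slot pSpike per-neuron per-bin spike probability.
#' @slot nBins number of time bins of the source raster.
#' @slot dMax maximum delay (bins).
#' @export
setClass("TEProfileSet",
  representation(te = "array", slte = "array", neuronIds = "character",
                 pSpike = "numeric", nBins = "integer", dMax = "integer"))

#' Rejection-threshold map on the (Strength, Sharpness) plane
#'
#' 25 x 25 (by default) pixel grid over the joint Strength/Sharpness
#' distribution of real and jitter-surrogate pairs. Each pixel holds
#' RT = N_jitt / (N_real + N_jitt); pixels containing no points are
#' undefined (NA) and treated as rejecting.
#'
#' @slot rt numeric matrix of RT values (NA where undefined).
#' @slot nReal,nJitt count matrices.
#' @slot strengthBreaks,sharpnessBreaks axis bin edges (Strength on log10
#'   when `logStrength`).
#' @slot logStrength whether the Strength axis is log10-scaled.
#' @export
setClass("RejectionMap",
  representation(rt = "matrix", nReal = "matrix", nJitt = "matrix",
                 strengthBreaks = "numeric", sharpnessBreaks = "numeric",
                 logStrength = "logical"))

#' Signed, directed effective network
#'
#' igraph-backed simple directed graph over neurons. Node attributes: `label`
#' ("E"/"I"), `rate_hz`, `layer`, and analysis results (`kcore`, `is_fvs`)
#' when computed. Edge attributes: `weight` (bias-adjusted strength), `sign`
#' (+1/-1, equal to the presynaptic label's sign), `peak_delay`, `sharpness`.
#'
#' @slot graph an `igraph` directed graph.
#' @export
setClass("EffectiveNetwork", representation(graph = "ANY"))

setValidity("EffectiveNetwork", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph must be an igraph object")
  if (!igraph::is_directed(g)) return("graph must be directed")
  if (any(igraph::which_multiple(g))) return("parallel edges are not allowed")
  TRUE
})

#' Minimum feedback vertex set result
#'
#' Output of the exact MFVS solver: the minimum set, its size, the solver
#' status, and (after [classifyFVSNodes()]) the critical / intermittent /
#' redundant classification of every node. Critical nodes belong to every
#' MFVS, intermittent to at least one but not all, redundant to none.
#'
#' @slot mfvs node names of one minimum feedback vertex set.
#' @slot size the proven optimal size (NA when unsolved).
#' @slot status "optimal" or "unsolved" (time limit reached).
#' @slot nodeClass named character: "critical", "intermittent", "redundant"
#'   or "undetermined" per node (empty until classified).
#' @export
setClass("FVSResult",
  representation(mfvs = "character", size = "integer", status = "character",
                 nodeClass = "character"),
  prototype(nodeClass = character(0)))
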