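#' @rdname SpikeTrainSet-class
setMethod("neuronIds", "SpikeTrainSet", function(x) x@neuronIds)

#' @rdname SpikeTrainSet-class
setMethod("spikeTimes", "SpikeTrainSet", function(x) {
  s <- x@spikes
  names(s) <- x@neuronIds
  s
})

#' @rdname SpikeTrainSet-class
setMethod("durationMs", "SpikeTrainSet", function(x) x@durationMs)

#' @rdname SpikeTrainSet-class
setMethod("nNeurons", "SpikeTrainSet", function(x) length(x@neuronIds))

#' @rdname SpikeTrainSet-class
setMethod("neuronInfo", "SpikeTrainSet", function(x) x@metadata)

setMethod("show", "SpikeTrainSet", function(object) {
  cat(sprintf("SpikeTrainSet: %d neurons, %.1f s, %d spikes\n",
              nNeurons(object), object@durationMs / 1000,
              sum(lengths(object@spikes))))
  if (!is.null(object@metadata))
    cat("  metadata:", paste(colnames(object@metadata), collapse = ", "), "\n")
})

#' @rdname BinnedRaster-class
setMethod("rasterMatrix", "BinnedRaster", function(x) x@mat)

#' @rdname BinnedRaster-class
setMethod("binWidth", "BinnedRaster", function(x) x@binMs)

#' @rdname BinnedRaster-class
setMethod("nBins", "BinnedRaster", function(x) ncol(x@mat))

#' @rdname BinnedRaster-class
setMethod("neuronIds", "BinnedRaster", function(x) x@neuronIds)

#' @rdname BinnedRaster-class
setMethod("nNeurons", "BinnedRaster", function(x) nrow(x@mat))

setMethod("show", "BinnedRaster", function(object) {
  cat(sprintf("BinnedRaster: %d neurons x %d bins (%.3g ms bins), %d spikes\n",
              nrow(object@mat), ncol(object@mat), object@binMs,
              length(object@mat@x)))
})

#' @rdname GroundTruthNetwork-class
#' @param x a GroundTruthNetwork
setMethod("neuronIds", "GroundTruthNetwork", function(x) x@neuronIds)

#' @describeIn GroundTruthNetwork-class true cell types, named by neuron id
#' @export
trueTypes <- function(x) {
  stopifnot(methods::is(x, "GroundTruthNetwork"))
  stats::setNames(x@types, x@neuronIds)
}

#' @describeIn GroundTruthNetwork-class signed adjacency matrix
#'   (`[target, source]`)
#' @export
trueAdjacency <- function(x) {
  stopifnot(methods::is(x, "GroundTruthNetwork"))
  x@adjacency
}

#' @describeIn GroundTruthNetwork-class integer delay matrix (ms)
#' @export
trueDelays <- function(x) {
  stopifnot(methods::is(x, "GroundTruthNetwork"))
  x@delays
}

setMethod("show", "GroundTruthNetwork", function(object) {
  cat(sprintf(
    "GroundTruthNetwork: %d neurons (%d E, %d I), %d connections\n",
    length(object@neuronIds), sum(object@types == "E"),
    sum(object@types == "I"), sum(object@adjacency != 0)))
})

setMethod("show", "TEDelayProfile", function(object) {
  cat(sprintf(
    "TEDelayProfile %s -> %s: Strength %.4g bits at d = %d ms, Sharpness %.3f, E-I bias %.3g\n",
    object@source, object@target, object@peakTe, object@peakDelay,
    object@sharpness, object@eiBias))
})

#' @rdname TEProfileSet-class
#' @param x a TEProfileSet
setMethod("neuronIds", "TEProfileSet", function(x) x@neuronIds)

setMethod("show", "TEProfileSet", function(object) {
  n <- length(object@neuronIds)
  cat(sprintf("TEProfileSet: %d neurons, delays 0..%d ms (%d ordered pairs)\n",
              n, object@dMax, n * (n - 1)))
})

#' @rdname EffectiveNetwork-class
setMethod("asIgraph", "EffectiveNetwork", function(x) x@graph)

#' @rdname EffectiveNetwork-class
#' @param x an EffectiveNetwork
setMethod("neuronIds", "EffectiveNetwork",
          function(x) igraph::V(x@graph)$name)

setMethod("show", "EffectiveNetwork", function(object) {
  g <- object@graph
  lab <- igraph::vertex_attr(g, "label")
  cat(sprintf("EffectiveNetwork: %d nodes, %d edges\n",
              igraph::vcount(g), igraph::ecount(g)))
  if (!is.null(lab))
    cat(sprintf("  labels: %d E, %d I\n", sum(lab == "E", na.rm = TRUE),
                sum(lab == "I", na.rm = TRUE)))
})

setMethod("show", "RejectionMap", function(object) {
  cat(sprintf("RejectionMap: %d x %d grid, %d real / %d surrogate points, %d defined pixels\n",
              nrow(object@rt), ncol(object@rt), sum(object@nReal),
              sum(object@nJitt), sum(!is.na(object@rt))))
})

setMethod("show", "FVSResult", function(object) {
  cat(sprintf("FVSResult: status %s, |MFVS| = %s\n", object@status,
              ifelse(is.na(object@size), "NA", object@size)))
  if (length(object@nodeClass)) {
    tb <- table(object@nodeClass)
    cat("  classes:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
})
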