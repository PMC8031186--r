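#' @rdname SpikeTrainSet-class
#' @param object,x a spikeTE object
#' @export
setGeneric("neuronIds", function(x) standardGeneric("neuronIds"))

#' @rdname SpikeTrainSet-class
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))

#' @rdname SpikeTrainSet-class
#' @export
setGeneric("durationMs", function(x) standardGeneric("durationMs"))

#' @rdname SpikeTrainSet-class
#' @export
setGeneric("nNeurons", function(x) standardGeneric("nNeurons"))

#' @rdname SpikeTrainSet-class
#' @export
setGeneric("neuronInfo", function(x) standardGeneric("neuronInfo"))

#' @rdname BinnedRaster-class
#' @export
setGeneric("rasterMatrix", function(x) standardGeneric("rasterMatrix"))

#' @rdname BinnedRaster-class
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' @rdname BinnedRaster-class
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @rdname EffectiveNetwork-class
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' Per-pair summary table of a profile set
#'
#' @param x a [TEProfileSet-class]
#' @param ... passed to methods
#' @return `data.frame` with one row per ordered pair (diagonal excluded):
#'   `source`, `target`, `peak_te` (Strength, bits), `peak_delay` (ms),
#'   `sharpness`, `ei_bias`, `te_nor`.
#' @export
setGeneric("pairStats", function(x, ...) standardGeneric("pairStats"))
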