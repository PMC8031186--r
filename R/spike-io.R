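#' Construct a SpikeTrainSet
#'
#' @param spikes list of numeric spike-time vectors (ms), one per neuron.
#'   Times are sorted and deduplicated at 0.001 ms resolution.
#' @param neuronIds character identifiers; defaults to `n1, n2, ...`.
#' @param durationMs recording duration; defaults to `ceiling(max time)` (an
#'   explicit value overrides).
#' @param metadata optional per-neuron `data.frame` (e.g. `depth_um`,
#'   `true_type`, `layer`).
#' @return a [SpikeTrainSet-class]
#' @export
SpikeTrainSet <- function(spikes, neuronIds = NULL, durationMs = NULL,
                          metadata = NULL) {
  spikes <- lapply(spikes, function(s) {
    s <- sort(as.numeric(s))
    s[!duplicated(round(s, 3))]
  })
  if (is.null(neuronIds)) neuronIds <- paste0("n", seq_along(spikes))
  if (is.null(durationMs)) {
    mx <- suppressWarnings(max(unlist(spikes), -Inf))
    durationMs <- if (is.finite(mx)) max(ceiling(mx), mx + 1e-9, 1) else 0
    # a spike exactly at an integer ms still needs duration > time
    if (is.finite(mx) && durationMs <= mx) durationMs <- durationMs + 1
  }
  methods::new("SpikeTrainSet", spikes = spikes,
               neuronIds = as.character(neuronIds),
               durationMs = as.numeric(durationMs), metadata = metadata)
}

#' Read a spike table (CSV/TSV)
#'
#' Expects columns `neuron_id` and `time_ms` (header required). Times must be
#' non-negative reals; per-neuron times are sorted on read. An empty file
#' (header only, or zero bytes) yields an empty SpikeTrainSet.
#'
#' @param path file path
#' @param dialect `"csv"` or `"tsv"`
#' @param durationMs optional explicit recording duration (ms); default is
#'   the maximum spike time rounded up to a whole ms.
#' @return a [SpikeTrainSet-class]
#' @export
readSpikeTable <- function(path, dialect = c("csv", "tsv"), durationMs = NULL) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  if (file.size(path) == 0)
    return(SpikeTrainSet(list(), character(0), durationMs = durationMs %||% 0))
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep,
                      colClasses = c("character", "character"),
                      col.names = c("neuron_id", "time_ms"), fill = FALSE),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e),
                             call. = FALSE))
  t_ms <- suppressWarnings(as.numeric(df$time_ms))
  bad <- which(is.na(t_ms))
  if (length(bad))
    stop(sprintf("parse error: non-numeric time_ms at line %d of %s",
                 bad[1] + 1L, path), call. = FALSE)
  neg <- which(t_ms < 0)
  if (length(neg))
    stop(sprintf("validation error: negative spike time at line %d of %s",
                 neg[1] + 1L, path), call. = FALSE)
  ids <- unique(df$neuron_id)
  spikes <- split(t_ms, factor(df$neuron_id, levels = ids))
  SpikeTrainSet(spikes, ids, durationMs = durationMs)
}

#' Write a spike table
#'
#' Spike times are written with 0.001 ms precision, so write-then-read
#' round-trips a SpikeTrainSet to that resolution.
#'
#' @param x a [SpikeTrainSet-class]
#' @param path output file
#' @param dialect `"csv"` or `"tsv"`
#' @export
writeSpikeTable <- function(x, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  df <- data.frame(
    neuron_id = rep(x@neuronIds, lengths(x@spikes)),
    time_ms = sprintf("%.3f", unlist(x@spikes)))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bin spike trains into a binary raster
#'
#' Bin t (0-based) covers the half-open interval `[t * binMs, (t+1) * binMs)`;
#' a bin is 1 iff at least one spike falls inside it (multiple spikes in one
#' bin collapse to a single 1). The raster has `floor(durationMs / binMs)`
#' bins.
#'
#' @param x a [SpikeTrainSet-class]
#' @param binMs bin width in ms (default 1)
#' @return a [BinnedRaster-class]
#' @export
binSpikes <- function(x, binMs = 1) {
  stopifnot(methods::is(x, "SpikeTrainSet"))
  if (binMs <= 0) stop("binMs must be > 0")
  nb <- floor(x@durationMs / binMs)
  n <- nNeurons(x)
  ii <- jj <- integer(0)
  if (n > 0) {
    bins <- lapply(x@spikes, function(s) unique(floor(s / binMs) + 1L))
    bins <- lapply(bins, function(b) b[b <= nb])
    ii <- rep(seq_len(n), lengths(bins))
    jj <- unlist(bins, use.names = FALSE)
    if (is.null(jj)) jj <- integer(0)
  }
  mat <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, nb))
  methods::new("BinnedRaster", mat = mat, binMs = binMs,
               neuronIds = x@neuronIds)
}

#' Per-neuron firing statistics
#'
#' @param r a [BinnedRaster-class] with at least one bin
#' @return `data.frame` with `neuron_id`, `p_spike` (per-bin spike
#'   probability) and `rate_hz`.
#' @export
firingRates <- function(r) {
  stopifnot(methods::is(r, "BinnedRaster"))
  if (nBins(r) < 1 || nNeurons(r) < 1) stop("empty raster")
  p <- Matrix::rowSums(r@mat) / nBins(r)
  data.frame(neuron_id = r@neuronIds, p_spike = as.numeric(p),
             rate_hz = as.numeric(p) * 1000 / r@binMs)
}

#' Remove low-rate neurons
#'
#' Neurons whose firing rate (spike count over the recording duration) is
#' strictly below `minHz` are dropped; survivor ordering and metadata are
#' preserved. The default 0.2 Hz is the conventional reliability floor for
#' sorted units in long MEA recordings.
#'
#' @param x a [SpikeTrainSet-class] with positive duration
#' @param minHz rate threshold in Hz
#' @return filtered [SpikeTrainSet-class]
#' @export
filterLowRate <- function(x, minHz = 0.2) {
  stopifnot(methods::is(x, "SpikeTrainSet"))
  if (nNeurons(x) == 0) return(x)
  if (x@durationMs <= 0) stop("durationMs must be > 0")
  rate <- lengths(x@spikes) / (x@durationMs / 1000)
  keep <- rate >= minHz
  methods::new("SpikeTrainSet", spikes = x@spikes[keep],
               neuronIds = x@neuronIds[keep], durationMs = x@durationMs,
               metadata = if (is.null(x@metadata)) NULL else
                 x@metadata[keep, , drop = FALSE])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
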