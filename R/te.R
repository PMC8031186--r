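#' @useDynLib spikeTE, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.spike_bins <- function(r) {
  # 1-based spike bin indices per neuron from a BinnedRaster
  m <- methods::as(r@mat, "TsparseMatrix")
  idx <- split(m@j + 1L, factor(m@i + 1L, levels = seq_len(nrow(m))))
  lapply(idx, function(b) sort(as.integer(b)))
}

.resolve_neuron <- function(r, id) {
  if (is.character(id)) {
    k <- match(id, r@neuronIds)
    if (is.na(k)) stop("unknown neuron id: ", id)
    k
  } else as.integer(id)
}

#' Delayed transfer entropy between two neurons
#'
#' Plug-in estimate (base-2 logarithm, bits) of the transfer entropy from
#' source neuron j to target neuron i at delay d, computed from the empirical
#' joint distribution of the binary triple (i_t, i_{t-1}, j_{t-d}). The sum
#' runs over t = max(1, d) .. n_bins - 1 (0-based) so that all three indices
#' exist; cells with zero joint probability contribute 0.
#'
#' @param r a [BinnedRaster-class]
#' @param source,target neuron id (character) or index; must differ
#' @param d delay in bins, `>= 0`
#' @return transfer entropy in bits (non-negative)
#' @export
transferEntropyAtDelay <- function(r, source, target, d) {
  .te_pair(r, source, target, d)$te
}

#' Sorted local transfer entropy at one delay
#'
#' Like [transferEntropyAtDelay()] but each local term is weighted by
#' `(-1)^(i_t - j_{t-d})`: +1 when target and delayed source show the same
#' event, -1 when they differ. The sum is positive for excitatory-like and
#' negative for inhibitory-like coupling.
#'
#' @inheritParams transferEntropyAtDelay
#' @return signed SLTE value in bits
#' @export
slteAtDelay <- function(r, source, target, d) {
  .te_pair(r, source, target, d)$slte
}

.te_pair <- function(r, source, target, d) {
  j <- .resolve_neuron(r, source)
  i <- .resolve_neuron(r, target)
  if (i == j) stop("source and target must differ")
  if (d < 0) stop("delay must be >= 0")
  if (nBins(r) < d + 2) stop("raster shorter than d + 2 bins")
  bins <- .spike_bins(r)
  res <- .te_slte_all_pairs_cpp(bins[i], bins[j], nBins(r), as.integer(d))
  list(te = res$te[1, 1, d + 1], slte = res$slte[1, 1, d + 1])
}

#' Sharpness of a TE delay curve
#'
#' Fraction of the total TE(d) mass (d = 0..dMax) contained in
#' d = 0..min(peakDelay + tau, dMax). Peaked curves score close to 1,
#' flat curves score low. Returns 0 when the curve is identically zero.
#' With `peakCentered = TRUE` the numerator window is
#' `peakDelay - tau .. peakDelay + tau` instead (the older coincidence-index
#' convention); the default starts at d = 0.
#'
#' @param teCurve numeric vector of TE values for delays 0..dMax
#' @param peakDelay delay (in bins) attaining the peak
#' @param tau window extension beyond the peak, ms (default 4)
#' @param peakCentered use a peak-centered window instead of starting at 0
#' @return sharpness in `[0, 1]`
#' @export
sharpness <- function(teCurve, peakDelay, tau = 4, peakCentered = FALSE) {
  if (tau < 0) stop("tau must be >= 0")
  dMax <- length(teCurve) - 1L
  tot <- sum(teCurve)
  if (tot <= 0) return(0)
  lo <- if (peakCentered) max(0L, peakDelay - tau) else 0L
  hi <- min(peakDelay + tau, dMax)
  sum(teCurve[(lo + 1L):(hi + 1L)]) / tot
}

#' Firing-rate-normalized peak transfer entropy
#'
#' Divides the peak TE by the magnitude of the target neuron's binary
#' entropy per bin, `|p log2 p + (1-p) log2(1-p)|`, removing the trivial
#' dependence of TE on the target's activity level. `p` is capped below at
#' `1 / nBins` when supplied; degenerate `p` in {0, 1} returns 0 with a
#' warning.
#'
#' @param peakTe peak TE in bits
#' @param pSpike target neuron per-bin spike probability
#' @param nBinsCap optional number of bins used to cap `pSpike` away from 0
#' @return normalized TE (dimensionless)
#' @export
teNormalized <- function(peakTe, pSpike, nBinsCap = NULL) {
  if (pSpike <= 0 || pSpike >= 1) {
    if (!is.null(nBinsCap) && pSpike <= 0) pSpike <- 1 / nBinsCap
    else {
      warning("degenerate spike probability; normalized TE set to 0")
      return(0)
    }
  }
  if (!is.null(nBinsCap)) pSpike <- max(pSpike, 1 / nBinsCap)
  h <- abs(pSpike * log2(pSpike) + (1 - pSpike) * log2(1 - pSpike))
  peakTe / h
}

.profile_summary <- function(te, slte, pSpikeTarget, nb, tau) {
  pk <- which.max(te) - 1L  # earliest delay attains ties
  peakTe <- te[pk + 1L]
  sh <- sharpness(te, pk, tau = tau)
  eiBias <- slte[pk + 1L]
  teNor <- if (peakTe > 0)
    teNormalized(peakTe, pSpikeTarget, nBinsCap = nb) else 0
  list(peakTe = peakTe, peakDelay = pk, sharpness = sh, eiBias = eiBias,
       teNor = teNor)
}

#' All-pairs TE/SLTE profiles
#'
#' Computes TE(d) and SLTE(d) for every ordered neuron pair of a raster over
#' delays 0..dMax in one vectorized pass. Optionally the source spike trains
#' may come from a second (e.g. jitter-surrogate) raster while targets stay
#' original.
#'
#' @param r a [BinnedRaster-class] providing the target trains
#' @param dMax maximum delay in bins (default 30, the conduction-delay
#'   search window)
#' @param sourceRaster optional [BinnedRaster-class] providing the source
#'   trains (defaults to `r`)
#' @return a [TEProfileSet-class]
#' @export
teAllPairs <- function(r, dMax = 30, sourceRaster = NULL) {
  stopifnot(methods::is(r, "BinnedRaster"))
  if (nBins(r) < dMax + 2) stop("raster shorter than dMax + 2 bins")
  tbins <- .spike_bins(r)
  sbins <- if (is.null(sourceRaster)) tbins else .spike_bins(sourceRaster)
  if (length(sbins) != length(tbins))
    stop("source raster must have the same neurons")
  res <- .te_slte_all_pairs_cpp(tbins, sbins, nBins(r), as.integer(dMax))
  p <- as.numeric(Matrix::rowSums(r@mat)) / nBins(r)
  methods::new("TEProfileSet", te = res$te, slte = res$slte,
               neuronIds = r@neuronIds, pSpike = p,
               nBins = as.integer(nBins(r)), dMax = as.integer(dMax))
}

#' TE delay profile for one ordered pair
#'
#' @inheritParams transferEntropyAtDelay
#' @param dMax maximum delay (default 30)
#' @param tau sharpness window extension (default 4 ms)
#' @return a [TEDelayProfile-class]
#' @export
teProfile <- function(r, source, target, dMax = 30, tau = 4) {
  j <- .resolve_neuron(r, source)
  i <- .resolve_neuron(r, target)
  if (i == j) stop("source and target must differ")
  bins <- .spike_bins(r)
  res <- .te_slte_all_pairs_cpp(bins[i], bins[j], nBins(r), as.integer(dMax))
  te <- res$te[1, 1, ]
  slte <- res$slte[1, 1, ]
  p <- length(bins[[i]]) / nBins(r)
  s <- .profile_summary(te, slte, p, nBins(r), tau)
  methods::new("TEDelayProfile", source = r@neuronIds[j],
               target = r@neuronIds[i], te = te, slte = slte,
               peakTe = s$peakTe, peakDelay = s$peakDelay,
               sharpness = s$sharpness, eiBias = s$eiBias, teNor = s$teNor)
}

#' Extract one pair's profile from an all-pairs set
#'
#' @param x a [TEProfileSet-class]
#' @param source,target neuron ids or indices
#' @param tau sharpness window extension (default 4)
#' @return a [TEDelayProfile-class]
#' @export
teProfileFromSet <- function(x, source, target, tau = 4) {
  j <- if (is.character(source)) match(source, x@neuronIds) else source
  i <- if (is.character(target)) match(target, x@neuronIds) else target
  te <- x@te[i, j, ]
  slte <- x@slte[i, j, ]
  s <- .profile_summary(te, slte, x@pSpike[i], x@nBins, tau)
  methods::new("TEDelayProfile", source = x@neuronIds[j],
               target = x@neuronIds[i], te = te, slte = slte,
               peakTe = s$peakTe, peakDelay = s$peakDelay,
               sharpness = s$sharpness, eiBias = s$eiBias, teNor = s$teNor)
}

#' @rdname pairStats
#' @param tau sharpness window extension in ms (default 4)
setMethod("pairStats", "TEProfileSet", function(x, tau = 4) {
  n <- length(x@neuronIds)
  nd <- x@dMax + 1L
  te <- x@te
  # peak over delays per (target, source)
  flat <- matrix(te, nrow = n * n, ncol = nd)
  pk_idx <- max.col(flat, ties.method = "first")
  peak <- flat[cbind(seq_len(n * n), pk_idx)]
  tot <- rowSums(flat)
  hi <- pmin(pk_idx - 1L + tau, x@dMax) + 1L
  csum <- t(apply(flat, 1, cumsum))
  num <- csum[cbind(seq_len(n * n), hi)]
  sharp <- ifelse(tot > 0, num / tot, 0)
  slte_flat <- matrix(x@slte, nrow = n * n, ncol = nd)
  bias <- slte_flat[cbind(seq_len(n * n), pk_idx)]
  tgt <- rep(seq_len(n), times = n)
  src <- rep(seq_len(n), each = n)
  p <- pmax(x@pSpike[tgt], 1 / x@nBins)
  h <- abs(p * log2(p) + (1 - p) * log2(1 - p))
  te_nor <- ifelse(peak > 0 & h > 0, peak / h, 0)
  df <- data.frame(source = x@neuronIds[src], target = x@neuronIds[tgt],
                   peak_te = peak, peak_delay = pk_idx - 1L,
                   sharpness = sharp, ei_bias = bias, te_nor = te_nor,
                   stringsAsFactors = FALSE)
  df[src != tgt, , drop = FALSE]
})
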