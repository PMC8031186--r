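#' Jitter surrogate raster
#'
#' Builds a surrogate raster in which each spike of the chosen presynaptic
#' neuron(s) is relocated, independently and uniformly, to one of the
#' currently silent bins within `windowBins` of its original bin (the
#' original bin itself excluded). A spike with no silent bin in its window
#' stays in place. Per-neuron spike counts are preserved exactly, so the
#' surrogate destroys millisecond timing while keeping rates.
#'
#' @param r a [BinnedRaster-class]
#' @param presyn neuron ids or indices to jitter (default: all neurons, the
#'   configuration used when every neuron acts as a candidate source)
#' @param windowBins half-width of the jitter window in bins (default 10,
#'   i.e. +/- 10 ms at 1 ms bins)
#' @param seed optional RNG seed
#' @return a [BinnedRaster-class]
#' @export
jitterSurrogate <- function(r, presyn = NULL, windowBins = 10, seed = NULL) {
  stopifnot(methods::is(r, "BinnedRaster"))
  if (windowBins < 1) stop("windowBins must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  idx <- if (is.null(presyn)) seq_len(nNeurons(r)) else
    vapply(presyn, function(p) .resolve_neuron(r, p), integer(1))
  bins <- .spike_bins(r)
  nb <- nBins(r)
  for (k in idx)
    bins[[k]] <- sort(.jitter_spikes_cpp(bins[[k]], nb,
                                         as.integer(windowBins)))
  ii <- rep(seq_along(bins), lengths(bins))
  jj <- unlist(bins, use.names = FALSE)
  if (is.null(jj)) jj <- integer(0)
  mat <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                              dims = c(nNeurons(r), nb))
  methods::new("BinnedRaster", mat = mat, binMs = r@binMs,
               neuronIds = r@neuronIds)
}

#' Rejection-threshold map over the (Strength, Sharpness) plane
#'
#' Pools real and surrogate pair summaries, grids the plane (Strength on
#' log10 by default, Sharpness linear) into `gridN` x `gridN` pixels whose
#' bounds cover the pooled points with 1% padding, and computes per pixel
#' RT = N_jitt / (N_real + N_jitt). Pixels containing no points are NA
#' (undefined) and treated as rejecting downstream. Pairs with non-positive
#' Strength are excluded (they are never selectable as connections).
#'
#' @param realPoints,surrogatePoints data.frames with columns `peak_te` (or
#'   `strength`) and `sharpness`
#' @param gridN grid resolution per axis (default 25)
#' @param logStrength log10-scale the Strength axis (default TRUE)
#' @return a [RejectionMap-class]
#' @export
rejectionMap <- function(realPoints, surrogatePoints, gridN = 25,
                         logStrength = TRUE) {
  getS <- function(df) if ("strength" %in% names(df)) df$strength else
    df$peak_te
  rs <- getS(realPoints); rh <- realPoints$sharpness
  ss <- getS(surrogatePoints); sh <- surrogatePoints$sharpness
  if (logStrength) {
    keep_r <- rs > 0; keep_s <- ss > 0
    rs <- log10(rs[keep_r]); rh <- rh[keep_r]
    ss <- log10(ss[keep_s]); sh <- sh[keep_s]
  }
  if (length(rs) == 0) stop("need at least one real point")
  allS <- c(rs, ss); allH <- c(rh, sh)
  if (length(unique(allS)) == 1 && length(unique(allH)) == 1)
    warning("all points identical: degenerate single-pixel map")
  pad <- function(v) {
    rng <- range(v)
    w <- diff(rng)
    if (w == 0) w <- max(abs(rng[1]), 1) * 1e-6
    c(rng[1] - 0.01 * w, rng[2] + 0.01 * w)
  }
  bS <- seq(pad(allS)[1], pad(allS)[2], length.out = gridN + 1)
  bH <- seq(pad(allH)[1], pad(allH)[2], length.out = gridN + 1)
  px <- function(s, h) {
    cbind(pmin(pmax(findInterval(s, bS, rightmost.closed = TRUE), 1), gridN),
          pmin(pmax(findInterval(h, bH, rightmost.closed = TRUE), 1), gridN))
  }
  count <- function(id) {
    m <- matrix(0, gridN, gridN)
    if (nrow(id)) for (k in seq_len(nrow(id))) m[id[k, 1], id[k, 2]] <-
        m[id[k, 1], id[k, 2]] + 1
    m
  }
  nR <- count(px(rs, rh))
  nJ <- count(px(ss, sh))
  rt <- nJ / (nR + nJ)
  rt[nR + nJ == 0] <- NA_real_
  methods::new("RejectionMap", rt = rt, nReal = nR, nJitt = nJ,
               strengthBreaks = bS, sharpnessBreaks = bH,
               logStrength = logStrength)
}

#' Select connected pairs from a rejection map
#'
#' A pair is accepted iff its pixel's RT is at most `rtThreshold` (default
#' 0.34). Pairs in undefined pixels, and pairs with non-positive Strength,
#' are not connected.
#'
#' @param realPoints data.frame as in [rejectionMap()]
#' @param map a [RejectionMap-class]
#' @param rtThreshold RT acceptance threshold
#' @return logical vector, one entry per row of `realPoints`
#' @export
selectConnections <- function(realPoints, map, rtThreshold = 0.34) {
  s <- if ("strength" %in% names(realPoints)) realPoints$strength else
    realPoints$peak_te
  h <- realPoints$sharpness
  ok <- rep(FALSE, length(s))
  usable <- if (map@logStrength) s > 0 else rep(TRUE, length(s))
  if (!any(usable)) return(ok)
  sv <- if (map@logStrength) log10(s[usable]) else s[usable]
  gi <- pmin(pmax(findInterval(sv, map@strengthBreaks,
                               rightmost.closed = TRUE), 1),
             nrow(map@rt))
  gj <- pmin(pmax(findInterval(h[usable], map@sharpnessBreaks,
                               rightmost.closed = TRUE), 1),
             ncol(map@rt))
  rt <- map@rt[cbind(gi, gj)]
  ok[usable] <- !is.na(rt) & rt <= rtThreshold
  ok
}

#' Bias-adjusted connection strength
#'
#' Real peak TE minus the mean surrogate peak TE of the same pair; the
#' shuffle baseline removes the finite-sample bias of the plug-in estimate.
#' May be negative for non-connections.
#'
#' @param teRealPeak real peak TE (bits)
#' @param teShufflePeaks per-surrogate peak TE values (at least one)
#' @return bias-adjusted strength (bits)
#' @export
biasAdjustedStrength <- function(teRealPeak, teShufflePeaks) {
  if (length(teShufflePeaks) < 1) stop("need at least one surrogate")
  teRealPeak - mean(teShufflePeaks)
}

#' Surrogate ensemble pair statistics
#'
#' Runs `nSurrogates` jitter surrogates in which every neuron's spike train
#' is relocated (each neuron is a candidate presynaptic source), recomputes
#' the all-pairs TE profiles with surrogate sources against original
#' targets, and returns the per-surrogate pair summary tables.
#'
#' @param r a [BinnedRaster-class]
#' @param nSurrogates number of surrogates (default 100)
#' @param windowBins jitter half-window in bins (default 10)
#' @param dMax,tau TE profile parameters
#' @param seed base seed; surrogate s uses `seed + s`
#' @return list of data.frames as returned by [pairStats()]
#' @export
surrogatePairStats <- function(r, nSurrogates = 100, windowBins = 10,
                               dMax = 30, tau = 4, seed = 1) {
  lapply(seq_len(nSurrogates), function(s) {
    surr <- jitterSurrogate(r, windowBins = windowBins, seed = seed + s)
    pairStats(teAllPairs(r, dMax = dMax, sourceRaster = surr), tau = tau)
  })
}

#' Assemble the signed effective network
#'
#' Full connection-selection stage: given per-neuron E/I labels (computed
#' first, as the four-category comparison requires), builds one rejection
#' map per connection category (E->E, E->I, I->E, I->I) from real and
#' jitter-surrogate (Strength, Sharpness) points, selects pairs at the RT
#' threshold separately per category, sets each accepted edge's weight to
#' its bias-adjusted strength and its sign to the presynaptic label's sign.
#'
#' @param r a [BinnedRaster-class]
#' @param labels named character vector ("E"/"I") per neuron
#' @param realStats optional precomputed [pairStats()] table
#' @param surrStats optional precomputed [surrogatePairStats()] list
#' @param nSurrogates,windowBins,dMax,tau,gridN,rtThreshold,seed parameters
#'   (paper defaults)
#' @param details return maps and the pair table alongside the network
#' @return an [EffectiveNetwork-class]; with `details = TRUE`, a list with
#'   elements `network`, `maps`, `pairs`
#' @export
assembleNetwork <- function(r, labels, realStats = NULL, surrStats = NULL,
                            nSurrogates = 100, windowBins = 10, dMax = 30,
                            tau = 4, gridN = 25, rtThreshold = 0.34,
                            seed = 1, details = FALSE) {
  stopifnot(methods::is(r, "BinnedRaster"))
  ids <- r@neuronIds
  labels <- labels[ids]
  if (anyNA(labels)) stop("labels must cover every neuron in the raster")
  if (is.null(realStats)) realStats <- pairStats(teAllPairs(r, dMax), tau)
  if (is.null(surrStats))
    surrStats <- surrogatePairStats(r, nSurrogates, windowBins, dMax, tau,
                                    seed)
  # mean surrogate peak per pair (tables share row order)
  surrPeak <- rowMeans(vapply(surrStats, function(df) df$peak_te,
                              numeric(nrow(realStats))))
  pairs <- realStats
  pairs$surr_peak <- surrPeak
  pairs$strength <- pairs$peak_te - surrPeak
  pairs$pre_label <- labels[pairs$source]
  pairs$post_label <- labels[pairs$target]
  pairs$connected <- FALSE
  maps <- list()
  for (pre in c("E", "I")) for (post in c("E", "I")) {
    cat_name <- paste0(pre, post)
    sel <- pairs$pre_label == pre & pairs$post_label == post
    if (!any(sel)) { message("category ", cat_name, ": no candidate pairs, skipped"); next }
    realPts <- pairs[sel, c("peak_te", "sharpness")]
    surrPts <- do.call(rbind, lapply(surrStats, function(df)
      df[sel, c("peak_te", "sharpness")]))
    if (all(realPts$peak_te <= 0)) next
    map <- rejectionMap(realPts, surrPts, gridN = gridN)
    maps[[cat_name]] <- map
    pairs$connected[sel] <- selectConnections(realPts, map, rtThreshold)
  }
  rates <- firingRates(r)
  acc <- pairs[pairs$connected, , drop = FALSE]
  edges <- data.frame(from = acc$source, to = acc$target,
                      weight = acc$strength,
                      sign = ifelse(acc$pre_label == "E", 1L, -1L),
                      peak_delay = acc$peak_delay,
                      sharpness = acc$sharpness, stringsAsFactors = FALSE)
  verts <- data.frame(name = ids, label = unname(labels),
                      rate_hz = rates$rate_hz, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = verts)
  net <- methods::new("EffectiveNetwork", graph = g)
  if (details) list(network = net, maps = maps, pairs = pairs) else net
}

#' Export an effective network
#'
#' GraphML keeps all node and edge attributes; the adjacency CSV holds the
#' signed weight matrix (rows = targets, columns = sources).
#'
#' @param x an [EffectiveNetwork-class]
#' @param path output file
#' @param format `"graphml"` or `"adjacency_csv"`
#' @export
writeNetwork <- function(x, path, format = c("graphml", "adjacency_csv")) {
  format <- match.arg(format)
  g <- asIgraph(x)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    A <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight"))
    sg <- as.matrix(igraph::as_adjacency_matrix(g, attr = "sign"))
    utils::write.csv(t(A * sg), path)  # rows = targets, signed weights
  }
  invisible(path)
}
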