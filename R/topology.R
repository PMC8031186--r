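#' Degree statistics
#'
#' Per-node in- and out-degree plus log10-binned degree histograms (the
#' standard view for long-tailed degree distributions).
#'
#' @param g an [EffectiveNetwork-class]
#' @param nBreaks number of log-spaced histogram bins
#' @return list with `degrees` (data.frame `node`, `in_degree`,
#'   `out_degree`) and `histIn` / `histOut` (data.frames `log10_mid`,
#'   `count`)
#' @export
degreeStats <- function(g, nBreaks = 10) {
  gr <- asIgraph(g)
  din <- igraph::degree(gr, mode = "in")
  dout <- igraph::degree(gr, mode = "out")
  logHist <- function(d) {
    d <- d[d > 0]
    if (!length(d)) return(data.frame(log10_mid = numeric(0),
                                      count = integer(0)))
    br <- seq(0, max(log10(d)) + 1e-9, length.out = nBreaks + 1)
    cut_idx <- pmin(findInterval(log10(d), br, rightmost.closed = TRUE),
                    nBreaks)
    data.frame(log10_mid = (br[-1] + br[-length(br)]) / 2,
               count = tabulate(cut_idx, nBreaks))
  }
  list(degrees = data.frame(node = igraph::V(gr)$name,
                            in_degree = as.integer(din),
                            out_degree = as.integer(dout),
                            stringsAsFactors = FALSE),
       histIn = logHist(din), histOut = logHist(dout))
}

#' k-core centrality (coreness)
#'
#' Coreness of every node: the largest k such that the node survives
#' recursive peeling of all nodes with degree below k. Computed by default
#' on the undirected simple projection (reciprocal edges collapsed, total
#' degree), which is the hierarchy-aware convention for signed directed
#' effective networks; in- or out-degree variants are available.
#'
#' @param g an [EffectiveNetwork-class]
#' @param mode `"total"` (undirected projection), `"in"`, or `"out"`
#' @return named integer vector of coreness values
#' @export
kcoreCentrality <- function(g, mode = c("total", "in", "out")) {
  mode <- match.arg(mode)
  gr <- asIgraph(g)
  if (mode == "total") {
    und <- igraph::as_undirected(gr, mode = "collapse")
    igraph::coreness(und)
  } else {
    igraph::coreness(gr, mode = mode)
  }
}

#' Anderson-Darling log-normality test
#'
#' Tests whether positive values follow a log-normal distribution by
#' applying the Anderson-Darling normality test (critical values for the
#' estimated-parameter case) to the log-transformed sample; the log-space
#' mean and s.d. are the fitted parameters.
#'
#' @param values positive numeric vector, length >= 8
#' @return list with `statistic` (AD), `p_value`, `mu`, `sigma`, `n`
#' @export
lognormalTest <- function(values) {
  if (any(values <= 0)) stop("values must be positive")
  if (length(values) < 8) stop("need at least 8 values")
  lv <- log(values)
  if (stats::sd(lv) == 0) stop("degenerate (constant) sample")
  ad <- nortest::ad.test(lv)
  list(statistic = unname(ad$statistic), p_value = ad$p.value,
       mu = mean(lv), sigma = stats::sd(lv), n = length(values))
}

# The 13 connected directed-triad classes, in the conventional census order
# (the same taxonomy the standard brain-connectivity motif routines use).
# Edge patterns, with A,B,C the three nodes:
#   021D  A<-B->C          111D  A<->B<-C        120D  A<-B->C, A<->C
#   021U  A->B<-C          111U  A<->B->C        120U  A->B<-C, A<->C
#   021C  A->B->C          030T  A->B<-C, A->C   120C  A->B->C, A<->C
#   030C  A->B->C->A       201   A<->B<->C       210   one null dyad short
#   300   fully reciprocal                              of 300
.motif_classes <- c("021D", "021U", "021C", "111D", "111U", "030T", "030C",
                    "201", "120D", "120U", "120C", "210", "300")

#' Triad motif census
#'
#' Counts every connected 3-node induced subgraph of a simple directed graph
#' into the standard 13-class directed-triad taxonomy (see
#' `spikeTE:::.motif_classes` for the adjacency patterns). With
#' `participation = TRUE` also returns, per node, the number of connected
#' triads the node takes part in, by class.
#'
#' @param g an [EffectiveNetwork-class]
#' @param participation also compute per-node participation counts (requires
#'   explicit triple enumeration; intended for moderate graphs)
#' @return named integer vector of 13 class counts; with participation, a
#'   list with `counts` and `participation` (nodes x classes matrix)
#' @export
triadMotifCensus <- function(g, participation = FALSE) {
  gr <- asIgraph(g)
  tc <- igraph::triad_census(gr)
  counts <- stats::setNames(as.integer(tc[4:16]), .motif_classes)
  if (!participation) return(counts)
  ids <- igraph::V(gr)$name
  A <- as.matrix(igraph::as_adjacency_matrix(gr)) > 0
  part <- matrix(0L, length(ids), 13, dimnames = list(ids, .motif_classes))
  und <- A | t(A)
  n <- length(ids)
  seen <- new.env(hash = TRUE)
  for (ctr in seq_len(n)) {
    nb <- which(und[ctr, ])
    if (length(nb) < 2) next
    cmb <- utils::combn(nb, 2)
    for (k in seq_len(ncol(cmb))) {
      tri <- sort(c(ctr, cmb[1, k], cmb[2, k]))
      key <- paste(tri, collapse = "-")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      cls <- .classify_triad(A[tri, tri])
      if (!is.na(cls)) part[tri, cls] <- part[tri, cls] + 1L
    }
  }
  list(counts = counts, participation = part)
}

# classify a 3x3 logical adjacency (no self loops) into one of the 13
# connected classes; NA when disconnected
.classify_triad <- function(S) {
  g3 <- igraph::graph_from_adjacency_matrix(S * 1, mode = "directed")
  tc <- igraph::triad_census(g3)
  hit <- which(tc == 1)
  if (hit <= 3) NA_integer_ else hit - 3L
}

#' Expected triad counts under the independent-dyad model
#'
#' Estimates the empirical dyad probabilities (null, single-direction,
#' reciprocal) of the graph and computes, combinatorially, the expected
#' count of each of the 13 connected triad classes if the three dyads of
#' every node triple were independent draws from those probabilities.
#' The observed/expected ratio flags over- or under-represented motifs.
#'
#' @param g an [EffectiveNetwork-class]
#' @return data.frame with `class`, `observed`, `expected`, `ratio`
#' @export
motifExpectedCounts <- function(g) {
  gr <- asIgraph(g)
  n <- igraph::vcount(gr)
  dc <- igraph::dyad_census(gr)
  npairs <- n * (n - 1) / 2
  p <- c(null = dc$null / npairs, asym = dc$asym / npairs,
         mut = dc$mut / npairs)
  # dyad states: 0 null, 1 a->b, 2 b->a, 3 mutual
  stateP <- c(p["null"], p["asym"] / 2, p["asym"] / 2, p["mut"])
  probs <- stats::setNames(numeric(13), .motif_classes)
  for (s12 in 0:3) for (s13 in 0:3) for (s23 in 0:3) {
    pr <- stateP[s12 + 1] * stateP[s13 + 1] * stateP[s23 + 1]
    if (pr == 0) next
    S <- matrix(FALSE, 3, 3)
    if (s12 %in% c(1, 3)) S[1, 2] <- TRUE
    if (s12 %in% c(2, 3)) S[2, 1] <- TRUE
    if (s13 %in% c(1, 3)) S[1, 3] <- TRUE
    if (s13 %in% c(2, 3)) S[3, 1] <- TRUE
    if (s23 %in% c(1, 3)) S[2, 3] <- TRUE
    if (s23 %in% c(2, 3)) S[3, 2] <- TRUE
    cls <- .classify_triad(S)
    if (!is.na(cls)) probs[cls] <- probs[cls] + pr
  }
  expected <- choose(n, 3) * probs
  observed <- triadMotifCensus(g)
  data.frame(class = .motif_classes, observed = as.integer(observed),
             expected = as.numeric(expected),
             ratio = ifelse(expected > 0, observed / expected, NA_real_),
             stringsAsFactors = FALSE)
}

#' Paired group comparison (Wilcoxon signed-rank)
#'
#' Compares paired per-dataset summaries of two groups (e.g. mean coreness
#' of excitatory vs inhibitory neurons per slice) with the Wilcoxon
#' signed-rank test, plus descriptive means and standard errors.
#'
#' @param x,y paired numeric vectors (same length; >= 5 pairs recommended)
#' @return list with `statistic`, `p_value`, `mean_x`, `mean_y`, `se_x`,
#'   `se_y`, `n`
#' @export
groupCompare <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  se <- function(v) stats::sd(v) / sqrt(length(v))
  if (all(x == y))  # all differences zero: no evidence of any difference
    return(list(statistic = 0, p_value = 1, mean_x = mean(x),
                mean_y = mean(y), se_x = se(x), se_y = se(y),
                n = length(x)))
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                            exact = FALSE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       mean_x = mean(x), mean_y = mean(y), se_x = se(x), se_y = se(y),
       n = length(x))
}
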