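# Independent brute-force oracles used across the suite. These deliberately
# re-derive every quantity with naive loops/enumeration, sharing no code with
# the package internals they check.

# plug-in TE and SLTE from an explicit 2x2x2 histogram
oracle_te_slte <- function(xi, xj, d) {
  T <- length(xi)
  t0 <- max(2, d + 1)
  a <- xi[t0:T]
  b <- xi[(t0 - 1):(T - 1)]
  cc <- xj[(t0 - d):(T - d)]
  Tv <- length(a)
  te <- 0; slte <- 0
  for (ai in 0:1) for (bi in 0:1) for (ci in 0:1) {
    n <- sum(a == ai & b == bi & cc == ci)
    if (n == 0) next
    nbc <- sum(b == bi & cc == ci)
    nab <- sum(a == ai & b == bi)
    nb <- sum(b == bi)
    loc <- log2((n / nbc) / (nab / nb))
    te <- te + n / Tv * loc
    slte <- slte + (if (ai == ci) 1 else -1) * n / Tv * loc
  }
  c(te = te, slte = slte)
}

# raster (0/1 matrix, neurons x bins) -> SpikeTrainSet with bin-centre times
raster_to_sts <- function(m) {
  SpikeTrainSet(lapply(seq_len(nrow(m)), function(i) which(m[i, ] == 1) - 0.5),
                durationMs = ncol(m))
}

random_raster <- function(n, T, p) matrix(rbinom(n * T, 1, p), n, T)

# coreness by literal recursive peeling on the undirected simple projection
oracle_coreness <- function(adj) {
  und <- (adj | t(adj)); diag(und) <- FALSE
  n <- nrow(und)
  core <- integer(n)
  alive <- rep(TRUE, n)
  k <- 0L
  while (any(alive)) {
    repeat {
      deg <- rowSums(und[, alive, drop = FALSE]) * alive
      low <- which(alive & deg < k + 1L)
      if (!length(low)) break
      core[low] <- k
      alive[low] <- FALSE
    }
    k <- k + 1L
    core[alive] <- k
  }
  core
}

# is a directed graph (logical adjacency, [from, to]) acyclic, self-loops
# counting as cycles -- Kahn's algorithm
oracle_is_acyclic <- function(adj) {
  if (any(diag(adj))) return(FALSE)
  alive <- rep(TRUE, nrow(adj))
  repeat {
    indeg <- colSums(adj[alive, alive, drop = FALSE])
    src <- which(alive)[indeg == 0]
    if (!length(src)) break
    alive[src] <- FALSE
  }
  !any(alive)
}

# minimum FVS size by subset enumeration in increasing cardinality
oracle_mfvs_size <- function(adj) {
  n <- nrow(adj)
  for (k in 0:n) {
    for (s in utils::combn(n, k, simplify = FALSE)) {
      a2 <- adj
      a2[, s] <- FALSE           # remove incoming edges to the set
      if (oracle_is_acyclic(a2)) return(k)
    }
  }
  n
}

# all MFVS sets (for critical/intermittent classification oracle)
oracle_all_mfvs <- function(adj) {
  n <- nrow(adj)
  k <- oracle_mfvs_size(adj)
  Filter(function(s) {
    a2 <- adj
    a2[, s] <- FALSE
    oracle_is_acyclic(a2)
  }, utils::combn(n, k, simplify = FALSE))
}

# connected-triad census by enumeration of all C(n,3) triples
oracle_triad_census <- function(adj) {
  n <- nrow(adj)
  counts <- integer(13)
  if (n < 3) return(counts)
  for (tri in utils::combn(n, 3, simplify = FALSE)) {
    S <- adj[tri, tri]
    und <- S | t(S)
    # weak connectivity of 3 nodes: at least 2 connected dyads
    ndy <- sum(und[upper.tri(und)])
    if (ndy < 2) next
    cls <- spikeTE:::.classify_triad(S)
    if (!is.na(cls)) counts[cls] <- counts[cls] + 1L
  }
  counts
}

net_from_adj <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj * 1, mode = "directed")
  igraph::V(g)$name <- paste0("v", seq_len(nrow(adj)))
  methods::new("EffectiveNetwork", graph = g)
}

random_adj <- function(n, p, loops = FALSE) {
  a <- matrix(runif(n * n) < p, n, n)
  if (!loops) diag(a) <- FALSE
  a
}
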