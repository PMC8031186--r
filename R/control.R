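#' Is a node set a feedback vertex set?
#'
#' A node subset is an FVS when deleting every edge whose head lies in the
#' subset leaves the directed graph acyclic (self-loops included: a
#' self-looped node must be in the set).
#'
#' @param g an [EffectiveNetwork-class]
#' @param s node names (may be empty)
#' @return logical
#' @export
isFVS <- function(g, s) {
  gr <- asIgraph(g)
  ids <- igraph::V(gr)$name
  if (!all(s %in% ids)) stop("unknown node in s")
  el <- igraph::as_edgelist(gr)
  keep <- !(el[, 2] %in% s)
  el <- el[keep, , drop = FALSE]
  if (any(el[, 1] == el[, 2])) return(FALSE)  # surviving self-loop
  g2 <- igraph::graph_from_data_frame(
    data.frame(from = el[, 1], to = el[, 2]), directed = TRUE,
    vertices = data.frame(name = ids))
  igraph::is_dag(g2)
}

# ---- exact MFVS solver -----------------------------------------------------
# Branch and bound on the condensed cycle structure:
#  * reductions: LOOP (self-looped node forced in, infeasible if forbidden),
#    IN0/OUT0 (acyclic-tail trimming), and when no nodes are forbidden,
#    IN1/OUT1 contraction (a node with a unique predecessor/successor is
#    dominated by it);
#  * branching on the vertices of a shortest cycle found by BFS;
#  * lower bound from a greedy vertex-disjoint cycle packing.
# Graphs are kept as out/in adjacency lists over 1..n with an alive mask.

.mk_graph <- function(n, edges) {
  adj_out <- vector("list", n); adj_in <- vector("list", n)
  for (v in seq_len(n)) { adj_out[[v]] <- integer(0); adj_in[[v]] <- integer(0) }
  if (nrow(edges)) {
    sp_o <- split(edges[, 2], edges[, 1])
    for (nm in names(sp_o)) adj_out[[as.integer(nm)]] <- unique(sp_o[[nm]])
    sp_i <- split(edges[, 1], edges[, 2])
    for (nm in names(sp_i)) adj_in[[as.integer(nm)]] <- unique(sp_i[[nm]])
  }
  list(out = adj_out, inn = adj_in, alive = rep(TRUE, n))
}

.g_del <- function(G, v) {
  for (w in G$out[[v]]) G$inn[[w]] <- setdiff(G$inn[[w]], v)
  for (w in G$inn[[v]]) G$out[[w]] <- setdiff(G$out[[w]], v)
  G$out[[v]] <- integer(0); G$inn[[v]] <- integer(0)
  G$alive[v] <- FALSE
  G
}

.g_add_edge <- function(G, u, v) {
  if (!(v %in% G$out[[u]])) {
    G$out[[u]] <- c(G$out[[u]], v)
    G$inn[[v]] <- c(G$inn[[v]], u)
  }
  G
}

# returns list(G, picked = solution nodes forced by reductions) or NULL if
# infeasible (a forbidden node carries a self-loop)
.reduce <- function(G, forbidden) {
  repeat {
    changed <- FALSE
    for (v in which(G$alive)) {
      if (!G$alive[v]) next
      if (v %in% G$out[[v]]) {            # LOOP
        if (forbidden[v]) return(NULL)
        G <- .g_del(G, v)
        G$picked <- c(G$picked, v)
        changed <- TRUE
        next
      }
      if (length(G$inn[[v]]) == 0 || length(G$out[[v]]) == 0) {  # IN0/OUT0
        G <- .g_del(G, v)
        changed <- TRUE
        next
      }
      if (!any(forbidden)) {
        if (length(G$inn[[v]]) == 1) {    # IN1: merge v into its predecessor
          u <- G$inn[[v]]
          succ <- G$out[[v]]
          G <- .g_del(G, v)
          for (w in succ) G <- if (w == u) .g_add_edge(G, u, u) else
            .g_add_edge(G, u, w)
          changed <- TRUE
          next
        }
        if (length(G$out[[v]]) == 1) {    # OUT1: merge v into its successor
          w <- G$out[[v]]
          pred <- G$inn[[v]]
          G <- .g_del(G, v)
          for (u in pred) G <- if (u == w) .g_add_edge(G, w, w) else
            .g_add_edge(G, u, w)
          changed <- TRUE
          next
        }
      }
    }
    if (!changed) return(G)
  }
}

# shortest directed cycle via BFS from each alive node (early-exit on short
# cycles); NULL when acyclic
.short_cycle <- function(G) {
  best <- NULL
  alive <- which(G$alive)
  for (s in alive) {
    # BFS over out-edges, looking for a path back to s
    dist <- rep(NA_integer_, length(G$alive))
    par <- rep(NA_integer_, length(G$alive))
    dist[s] <- 0L
    q <- s
    found <- FALSE
    while (length(q) && !found) {
      v <- q[1]; q <- q[-1]
      if (!is.null(best) && dist[v] + 1L >= length(best)) break
      for (w in G$out[[v]]) {
        if (w == s) {
          cyc <- v
          while (cyc[1] != s) cyc <- c(par[cyc[1]], cyc)
          best <- cyc
          found <- TRUE
          break
        }
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          par[w] <- v
          q <- c(q, w)
        }
      }
    }
    if (!is.null(best) && length(best) == 2) break
  }
  best
}

# greedy vertex-disjoint cycle packing size (lower bound on FVS size)
.cycle_packing_lb <- function(G) {
  lb <- 0L
  repeat {
    cyc <- .short_cycle(G)
    if (is.null(cyc)) return(lb)
    lb <- lb + 1L
    for (v in cyc) G <- .g_del(G, v)
    G <- .reduce0(G)
  }
}

# trimming-only reduction used inside the lower bound
.reduce0 <- function(G) {
  repeat {
    dead <- which(G$alive & (lengths(G$inn) == 0 | lengths(G$out) == 0))
    dead <- dead[!vapply(dead, function(v) v %in% G$out[[v]], logical(1))]
    if (!length(dead)) return(G)
    for (v in dead) G <- .g_del(G, v)
  }
}

.mfvs_env <- function() new.env(parent = emptyenv())

.bb <- function(G, acc, forbidden, st) {
  if (Sys.time() > st$deadline) { st$timeout <- TRUE; return(invisible()) }
  G$picked <- integer(0)
  G <- .reduce(G, forbidden)
  if (is.null(G)) return(invisible())           # infeasible branch
  acc <- c(acc, G$picked)
  if (length(acc) >= st$best_size) return(invisible())
  cyc <- .short_cycle(G)
  if (is.null(cyc)) {                           # acyclic: feasible solution
    st$best_size <- length(acc)
    st$best_set <- acc
    return(invisible())
  }
  lb <- .cycle_packing_lb(G)
  if (length(acc) + lb >= st$best_size) return(invisible())
  for (v in cyc) {
    if (forbidden[v]) next
    .bb(.g_del(G, v), c(acc, v), forbidden, st)
    if (st$timeout) return(invisible())
  }
  invisible()
}

.solve_mfvs <- function(n, edges, forbidden_idx = integer(0),
                        time_limit = 60) {
  G <- .mk_graph(n, edges)
  forbidden <- rep(FALSE, n)
  forbidden[forbidden_idx] <- TRUE
  st <- .mfvs_env()
  st$best_size <- n + 1L        # every-non-forbidden-node fallback may fail,
  st$best_set <- NULL           # so start above any feasible size
  st$timeout <- FALSE
  st$deadline <- Sys.time() + time_limit
  .bb(G, integer(0), forbidden, st)
  if (st$timeout) return(list(status = "unsolved", size = NA_integer_,
                              set = NULL))
  if (is.null(st$best_set) && st$best_size > n)
    return(list(status = "infeasible", size = NA_integer_, set = NULL))
  list(status = "optimal", size = st$best_size,
       set = sort(unique(st$best_set)))
}

#' Minimum feedback vertex set (exact)
#'
#' Computes a provably minimum feedback vertex set of a directed graph with
#' an exact branch-and-bound search (self-looped nodes forced in,
#' acyclic-tail trimming and unique-neighbor contraction reductions,
#' shortest-cycle branching, disjoint-cycle-packing lower bound). If the
#' time limit is reached before optimality is proven the result is reported
#' as `"unsolved"` -- never a silent heuristic answer.
#'
#' @param g an [EffectiveNetwork-class]
#' @param solverTimeLimit wall-clock budget in seconds
#' @return an [FVSResult-class]; the returned set always passes [isFVS()]
#' @export
mfvs <- function(g, solverTimeLimit = 60) {
  gr <- asIgraph(g)
  ids <- igraph::V(gr)$name
  el <- igraph::as_edgelist(gr, names = FALSE)
  res <- .solve_mfvs(length(ids), el, time_limit = solverTimeLimit)
  if (res$status != "optimal")
    return(methods::new("FVSResult", mfvs = character(0),
                        size = NA_integer_, status = res$status))
  out <- methods::new("FVSResult", mfvs = ids[res$set],
                      size = as.integer(res$size), status = "optimal")
  stopifnot(isFVS(g, out@mfvs))
  out
}

#' Classify nodes as critical, intermittent, or redundant
#'
#' A node is critical when it belongs to every MFVS (forbidding it raises
#' the optimum), intermittent when it belongs to at least one MFVS but not
#' all, and redundant when no MFVS contains it. Decided by two exact
#' re-solves per candidate node (forcing the node out, then in); nodes whose
#' subproblems hit the per-node time limit are `"undetermined"`. Nodes that
#' lie on no directed cycle are redundant without re-solving.
#'
#' @param g an [EffectiveNetwork-class]
#' @param res optimal [FVSResult-class] for `g` (from [mfvs()])
#' @param perNodeTimeLimit seconds per ILP-style re-solve
#' @return the [FVSResult-class] with `nodeClass` filled
#' @export
classifyFVSNodes <- function(g, res, perNodeTimeLimit = 30) {
  if (res@status != "optimal") stop("base MFVS must be solved to optimality")
  gr <- asIgraph(g)
  ids <- igraph::V(gr)$name
  el <- igraph::as_edgelist(gr, names = FALSE)
  n <- length(ids)
  base <- res@size
  cls <- stats::setNames(rep("redundant", n), ids)
  # only nodes on some directed cycle can ever enter an MFVS: nodes in a
  # non-trivial strongly connected component, or with a self-loop
  scc <- igraph::components(gr, mode = "strong")
  loops <- el[el[, 1] == el[, 2], 1]
  cyc_nodes <- union(which(scc$membership %in%
                             which(scc$csize >= 2)), loops)
  for (v in cyc_nodes) {
    out_res <- .solve_mfvs(n, el, forbidden_idx = v,
                           time_limit = perNodeTimeLimit)
    if (out_res$status == "unsolved") { cls[v] <- "undetermined"; next }
    critical <- out_res$status == "infeasible" || out_res$size > base
    if (critical) { cls[v] <- "critical"; next }
    # in-some test: delete v (forcing it into the set) and compare 1 + opt
    el_v <- el[el[, 1] != v & el[, 2] != v, , drop = FALSE]
    in_res <- .solve_mfvs(n, el_v, time_limit = perNodeTimeLimit)
    if (in_res$status == "unsolved") { cls[v] <- "undetermined"; next }
    cls[v] <- if (1L + in_res$size == base) "intermittent" else "redundant"
  }
  methods::initialize(res, nodeClass = cls)
}

#' E/I composition of the feedback vertex set and k-core overlap
#'
#' FVS ratio per cell class (share of excitatory / inhibitory neurons that
#' are FVS members), the overlap of the FVS with the maximal-coreness node
#' set, and a per-layer breakdown when layer labels are present.
#'
#' @param g an [EffectiveNetwork-class] with node attribute `label`
#' @param res an optimal [FVSResult-class]
#' @param kcore named coreness vector (from [kcoreCentrality()])
#' @return list with `ratio_E`, `ratio_I`, `overlap` (named:
#'   `fvs_in_kcmax_over_fvs`, `fvs_in_kcmax_over_kcmax`), `kc_max`, and
#'   optionally `by_layer`
#' @export
fvsGroupReport <- function(g, res, kcore) {
  gr <- asIgraph(g)
  ids <- igraph::V(gr)$name
  lab <- igraph::vertex_attr(gr, "label")
  if (is.null(lab)) stop("network has no E/I labels")
  names(lab) <- ids
  fvs <- res@mfvs
  ratio <- function(sel) {
    if (!any(sel)) return(NA_real_)
    sum(ids[sel] %in% fvs) / sum(sel)
  }
  kc_max <- max(kcore)
  kmax_set <- names(kcore)[kcore == kc_max]
  ov1 <- if (length(fvs)) sum(fvs %in% kmax_set) / length(fvs) else NA_real_
  ov2 <- if (length(kmax_set)) sum(kmax_set %in% fvs) / length(kmax_set) else
    NA_real_
  out <- list(ratio_E = ratio(lab == "E"), ratio_I = ratio(lab == "I"),
              overlap = c(fvs_in_kcmax_over_fvs = ov1,
                          fvs_in_kcmax_over_kcmax = ov2),
              kc_max = kc_max)
  layer <- igraph::vertex_attr(gr, "layer")
  if (!is.null(layer)) {
    out$by_layer <- do.call(rbind, lapply(unique(layer), function(L) {
      data.frame(layer = L,
                 ratio_E = ratio(lab == "E" & layer == L),
                 ratio_I = ratio(lab == "I" & layer == L))
    }))
  }
  out
}
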