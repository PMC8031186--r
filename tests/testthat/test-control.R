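triangle <- function() {
  adj <- matrix(FALSE, 3, 3)
  adj[1, 2] <- adj[2, 3] <- adj[3, 1] <- TRUE
  adj
}

test_that("isFVS checks acyclicity after removing incoming edges", {
  net <- net_from_adj(triangle())
  expect_true(isFVS(net, "v1"))
  expect_false(isFVS(net, character(0)))
  dag <- matrix(FALSE, 4, 4); dag[1, 2] <- dag[2, 3] <- dag[1, 4] <- TRUE
  expect_true(isFVS(net_from_adj(dag), character(0)))
  expect_error(isFVS(net, "nope"), "unknown")
})

test_that("exact MFVS solves canonical instances", {
  dag <- matrix(FALSE, 5, 5); dag[upper.tri(dag)] <- TRUE
  expect_equal(mfvs(net_from_adj(dag))@size, 0L)
  # single n-cycle: size 1
  n <- 7
  cyc <- matrix(FALSE, n, n)
  for (k in 1:n) cyc[k, k %% n + 1] <- TRUE
  res <- mfvs(net_from_adj(cyc))
  expect_equal(res@size, 1L)
  expect_true(isFVS(net_from_adj(cyc), res@mfvs))
})

test_that("ILP-grade optimality matches exhaustive enumeration", {
  set.seed(41)
  for (rep in 1:40) {
    n <- sample(4:8, 1)
    adj <- random_adj(n, runif(1, 0.15, 0.5))
    net <- net_from_adj(adj)
    res <- mfvs(net, solverTimeLimit = 30)
    expect_equal(res@status, "optimal")
    expect_equal(res@size, oracle_mfvs_size(adj))
    expect_true(isFVS(net, res@mfvs))
    # no strict subset of the returned set is an FVS
    if (res@size > 0) {
      for (drop in seq_along(res@mfvs))
        expect_false(isFVS(net, res@mfvs[-drop]))
    }
  }
})

test_that("MFVS size is monotone under edge addition", {
  set.seed(43)
  n <- 7
  full <- which(random_adj(n, 0.5), arr.ind = TRUE)
  ord <- sample(nrow(full))
  sizes <- sapply(c(10, 20, nrow(full)), function(k) {
    adj <- matrix(FALSE, n, n)
    adj[full[ord[seq_len(min(k, nrow(full)))], , drop = FALSE]] <- TRUE
    mfvs(net_from_adj(adj))@size
  })
  expect_true(all(diff(sizes) >= 0))
})

test_that("critical/intermittent/redundant classes match enumeration", {
  # two 2-cycles sharing node a: a critical, b and c redundant
  adj <- matrix(FALSE, 3, 3)
  adj[1, 2] <- adj[2, 1] <- adj[1, 3] <- adj[3, 1] <- TRUE
  net <- net_from_adj(adj)
  res <- classifyFVSNodes(net, mfvs(net))
  expect_equal(unname(res@nodeClass), c("critical", "redundant", "redundant"))

  # DAG: everything redundant
  dag <- matrix(FALSE, 3, 3); dag[1, 2] <- dag[2, 3] <- TRUE
  netd <- net_from_adj(dag)
  resd <- classifyFVSNodes(netd, mfvs(netd))
  expect_true(all(resd@nodeClass == "redundant"))

  # self-loop nodes are critical
  lp <- matrix(FALSE, 2, 2); lp[1, 1] <- TRUE; lp[1, 2] <- TRUE
  netl <- net_from_adj(lp)
  resl <- classifyFVSNodes(netl, mfvs(netl))
  expect_equal(unname(resl@nodeClass["v1"]), "critical")

  # random instances vs enumeration of all minimum sets
  set.seed(47)
  for (rep in 1:12) {
    n <- sample(4:7, 1)
    adj <- random_adj(n, runif(1, 0.2, 0.5))
    net <- net_from_adj(adj)
    res <- classifyFVSNodes(net, mfvs(net))
    all_sets <- oracle_all_mfvs(adj)
    in_all <- Reduce(intersect, all_sets)
    in_some <- unique(unlist(all_sets))
    want <- rep("redundant", n)
    want[in_some] <- "intermittent"
    want[in_all] <- "critical"
    if (length(all_sets) && length(all_sets[[1]]) == 0) want <- rep("redundant", n)
    expect_equal(unname(res@nodeClass), want)
  }
})

test_that("FVS group report computes ratios and k-core overlap", {
  adj <- matrix(FALSE, 5, 5)
  adj[1, 2] <- adj[2, 1] <- TRUE   # one 2-cycle among v1, v2
  net <- net_from_adj(adj)
  g <- asIgraph(net)
  igraph::V(g)$label <- c("I", "E", "E", "E", "E")
  net <- methods::new("EffectiveNetwork", graph = g)
  res <- mfvs(net)
  kc <- kcoreCentrality(net)
  rep_ <- fvsGroupReport(net, res, kc)
  expect_equal(res@size, 1L)
  if (res@mfvs == "v1") {
    expect_equal(rep_$ratio_I, 1)
    expect_equal(rep_$ratio_E, 0)
  } else {
    expect_equal(rep_$ratio_I, 0)
    expect_equal(rep_$ratio_E, 0.25)
  }
  # FVS inside the maximal core -> first overlap fraction 1
  expect_equal(unname(rep_$overlap["fvs_in_kcmax_over_fvs"]), 1)
})

test_that("the solver reports unsolved rather than guessing on timeout", {
  set.seed(53)
  adj <- random_adj(40, 0.5)
  res <- mfvs(net_from_adj(adj), solverTimeLimit = 1e-4)
  expect_equal(res@status, "unsolved")
  expect_true(is.na(res@size))
})
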