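test_that("degree statistics conserve edge counts", {
  g <- randomDirectedGraph(20, 0.2, pBidir = 0.3, seed = 13)
  ds <- degreeStats(g)
  m <- igraph::ecount(asIgraph(g))
  expect_equal(sum(ds$degrees$in_degree), m)
  expect_equal(sum(ds$degrees$out_degree), m)
  expect_equal(sum(ds$histIn$count), sum(ds$degrees$in_degree > 0))
  e <- randomDirectedGraph(5, 0)
  expect_true(all(degreeStats(e)$degrees$in_degree == 0))
})

test_that("coreness matches the peeling oracle and known graphs", {
  # star: every node coreness 1
  star <- igraph::make_star(8, mode = "out")
  igraph::V(star)$name <- paste0("v", 1:8)
  expect_true(all(kcoreCentrality(
    methods::new("EffectiveNetwork", graph = star)) == 1))
  # complete bidirectional K4: coreness 3
  k4 <- igraph::make_full_graph(4, directed = TRUE)
  igraph::V(k4)$name <- paste0("v", 1:4)
  expect_true(all(kcoreCentrality(
    methods::new("EffectiveNetwork", graph = k4)) == 3))
  # random graphs vs brute-force peeling + nesting property
  set.seed(17)
  for (rep in 1:40) {
    n <- sample(4:10, 1)
    adj <- random_adj(n, runif(1, 0.1, 0.5))
    net <- net_from_adj(adj)
    kc <- kcoreCentrality(net)
    expect_equal(unname(kc), oracle_coreness(adj))
    for (k in seq_len(max(kc))) {
      expect_true(all(names(kc)[kc >= k + 1] %in% names(kc)[kc >= k]))
    }
  }
})

test_that("the AD log-normality test is calibrated and has power", {
  set.seed(19)
  rej <- replicate(100, lognormalTest(rlnorm(1000))$p_value < 0.01)
  expect_gte(mean(!rej), 0.95)
  expect_lt(lognormalTest(rexp(10000))$p_value, 0.001)
  fit <- lognormalTest(rlnorm(20000, meanlog = 1, sdlog = 0.5))
  expect_lt(abs(fit$mu - 1), 0.05)
  expect_lt(abs(fit$sigma - 0.5), 0.05)
  expect_error(lognormalTest(c(-1, rep(2, 10))), "positive")
  expect_error(lognormalTest(rep(3, 20)), "degenerate")
  expect_error(lognormalTest(rlnorm(5)), "at least 8")
})

test_that("triad census equals brute-force triple enumeration", {
  tri <- matrix(TRUE, 3, 3); diag(tri) <- FALSE
  counts <- triadMotifCensus(net_from_adj(tri))
  expect_equal(sum(counts), 1)
  expect_equal(unname(counts["300"]), 1)
  empty <- triadMotifCensus(net_from_adj(matrix(FALSE, 4, 4)))
  expect_true(all(empty == 0))
  set.seed(23)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    adj <- random_adj(n, runif(1, 0.1, 0.6))
    counts <- triadMotifCensus(net_from_adj(adj))
    expect_equal(unname(counts), oracle_triad_census(adj))
  }
})

test_that("motif participation is consistent with the class counts", {
  set.seed(29)
  adj <- random_adj(7, 0.4)
  res <- triadMotifCensus(net_from_adj(adj), participation = TRUE)
  # each triad contributes its 3 nodes once
  expect_equal(colSums(res$participation), 3 * as.integer(res$counts),
               ignore_attr = TRUE)
})

test_that("dyad-model expectations calibrate on Erdos-Renyi graphs", {
  set.seed(31)
  g <- randomDirectedGraph(200, 0.04, pBidir = 0.2, seed = 31)
  tab <- motifExpectedCounts(g)
  expect_equal(nrow(tab), 13)
  # total expectation close to total observation on an independent-dyad graph
  expect_lt(abs(sum(tab$observed) - sum(tab$expected)) /
            sum(tab$expected), 0.25)
  big <- tab[tab$expected >= 20, ]
  expect_true(all(abs(big$ratio - 1) < 0.5))
  # no reciprocal dyads -> zero expectation for every mutual-containing class
  g2 <- randomDirectedGraph(50, 0.1, pBidir = 0, seed = 5)
  tab2 <- motifExpectedCounts(g2)
  mutual_classes <- c("111D", "111U", "201", "120D", "120U", "120C", "210",
                      "300")
  expect_true(all(tab2$expected[tab2$class %in% mutual_classes] == 0))
})

test_that("paired signed-rank comparison behaves at the boundaries", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(groupCompare(x, x)$p_value, 1)
  res <- groupCompare(x, x + 2)
  expect_lt(res$p_value, 0.05)
  expect_equal(res$mean_y - res$mean_x, 2)
  expect_error(groupCompare(1:3, 1:4), "equal length")
  # type-I error near nominal under the null
  set.seed(37)
  pv <- replicate(400, groupCompare(rnorm(12), rnorm(12))$p_value)
  expect_lt(abs(mean(pv < 0.05) - 0.05), 0.035)
})
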