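test_that("jitter surrogates conserve spike counts and stay in-window", {
  set.seed(61)
  m <- random_raster(5, 2000, 0.1)
  r <- binSpikes(raster_to_sts(m))
  surr <- jitterSurrogate(r, windowBins = 10, seed = 1)
  expect_equal(Matrix::rowSums(rasterMatrix(surr)),
               Matrix::rowSums(rasterMatrix(r)))
  for (i in 1:5) {
    b0 <- which(m[i, ] == 1)
    b1 <- which(as.numeric(rasterMatrix(surr)[i, ]) == 1)
    # every surrogate spike lies within 10 bins of some original spike
    expect_true(all(vapply(b1, function(b) min(abs(b - b0)) <= 10,
                           logical(1))))
  }
})

test_that("a lone spike lands uniformly on the 20 silent bins around it", {
  m <- matrix(0, 1, 101); m[1, 51] <- 1
  r <- binSpikes(raster_to_sts(m))
  set.seed(99)
  land <- replicate(10000, {
    s <- jitterSurrogate(r, windowBins = 10)
    which(as.numeric(rasterMatrix(s)[1, ]) == 1)
  })
  expect_true(all(land %in% setdiff(41:61, 51)))
  tab <- table(factor(land, levels = setdiff(41:61, 51)))
  p <- 1 / 20
  sigma <- sqrt(10000 * p * (1 - p))
  expect_true(all(abs(tab - 10000 * p) < 4 * sigma))
})

test_that("fully occupied windows leave the raster unchanged", {
  m <- matrix(1, 2, 50)
  r <- binSpikes(raster_to_sts(m))
  surr <- jitterSurrogate(r, seed = 1)
  expect_equal(as.matrix(rasterMatrix(surr)), as.matrix(rasterMatrix(r)))
})

test_that("rejection-threshold pixels follow the count ratio", {
  real <- data.frame(peak_te = c(1, 1, 10), sharpness = c(0.2, 0.2, 0.9))
  surr <- data.frame(peak_te = c(1, 0.01, 0.01, 0.01, 0.01, 0.01),
                     sharpness = c(0.2, 0.1, 0.1, 0.1, 0.1, 0.1))
  map <- rejectionMap(real, surr, gridN = 5)
  # pixel of the (1, 0.2) points: 2 real + 1 surrogate -> RT = 1/3
  sel <- selectConnections(real, map, rtThreshold = 0.34)
  expect_true(sel[1] && sel[2])       # 0.333 <= 0.34
  expect_true(sel[3])                 # real-only pixel, RT = 0
  expect_equal(sum(map@nReal), 3)
  expect_equal(sum(map@nJitt), 6)
  rt_vals <- map@rt[!is.na(map@rt)]
  expect_true(any(abs(rt_vals - 1 / 3) < 1e-12))
  expect_true(any(rt_vals == 1))      # surrogate-only pixel
  expect_true(any(is.na(map@rt)))     # empty pixels undefined
})

test_that("pairs above the RT threshold or in undefined pixels are rejected", {
  real <- data.frame(peak_te = c(1, 2), sharpness = c(0.5, 0.5))
  surr <- data.frame(peak_te = rep(c(1, 2), c(2, 2)),
                     sharpness = rep(0.5, 4))
  map <- rejectionMap(real, surr, gridN = 2)
  expect_false(any(selectConnections(real, map, rtThreshold = 0.34)))
  # non-positive strength is never selectable
  real2 <- data.frame(peak_te = c(0, 1), sharpness = c(0.5, 0.5))
  expect_equal(selectConnections(real2, map)[1], FALSE)
})

test_that("bias-adjusted strength subtracts the mean surrogate peak", {
  expect_equal(biasAdjustedStrength(0.10, c(0.02, 0.02)), 0.08)
  expect_equal(biasAdjustedStrength(0.05, rep(0.05, 10)), 0)
  expect_error(biasAdjustedStrength(0.1, numeric(0)), "surrogate")
})

test_that("assembled networks have label-consistent edge signs", {
  set.seed(71)
  sim <- simulateIzhikevich(16, 4, pConnect = 0.15, durationMs = 120000,
                            seed = 4)
  r <- binSpikes(sim$spikes)
  lab <- trueTypes(sim$truth)
  asm <- assembleNetwork(r, lab, nSurrogates = 5, seed = 4, details = TRUE)
  g <- asIgraph(asm$network)
  if (igraph::ecount(g) > 0) {
    el <- igraph::as_edgelist(g)
    expect_equal(igraph::E(g)$sign,
                 unname(ifelse(lab[el[, 1]] == "E", 1L, -1L)))
  }
  # shuffled labels: signs still follow the (shuffled) presynaptic label
  lab2 <- setNames(sample(lab), names(lab))
  asm2 <- assembleNetwork(r, lab2, realStats = asm$pairs[,
    c("source", "target", "peak_te", "peak_delay", "sharpness", "ei_bias",
      "te_nor")], nSurrogates = 5, seed = 4, details = TRUE)
  g2 <- asIgraph(asm2$network)
  if (igraph::ecount(g2) > 0) {
    el2 <- igraph::as_edgelist(g2)
    expect_equal(igraph::E(g2)$sign,
                 unname(ifelse(lab2[el2[, 1]] == "E", 1L, -1L)))
  }
})

test_that("network export round-trips through GraphML", {
  sim <- simulateIzhikevich(8, 2, pConnect = 0.3, durationMs = 30000,
                            seed = 6)
  r <- binSpikes(sim$spikes)
  asm <- assembleNetwork(r, trueTypes(sim$truth), nSurrogates = 3, seed = 6,
                         details = TRUE)
  f <- tempfile(fileext = ".graphml")
  writeNetwork(asm$network, f)
  g2 <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(g2), igraph::vcount(asIgraph(asm$network)))
  expect_equal(igraph::ecount(g2), igraph::ecount(asIgraph(asm$network)))
})
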