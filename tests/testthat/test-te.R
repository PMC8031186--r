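test_that("TE and SLTE match the naive histogram oracle exactly", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(2:5, 1)
    T <- sample(100:500, 1)
    m <- random_raster(n, T, runif(1, 0.05, 0.4))
    r <- binSpikes(raster_to_sts(m))
    prof <- teAllPairs(r, dMax = 8)
    for (pair in list(c(1, 2), c(2, 1))) {
      i <- pair[1]; j <- pair[2]
      for (d in c(0, 1, 5, 8)) {
        o <- oracle_te_slte(m[i, ], m[j, ], d)
        expect_equal(transferEntropyAtDelay(r, j, i, d), unname(o["te"]),
                     tolerance = 1e-12)
        expect_equal(slteAtDelay(r, j, i, d), unname(o["slte"]),
                     tolerance = 1e-12)
        # vectorized all-pairs equals the per-pair path exactly
        expect_identical(prof@te[i, j, d + 1],
                         transferEntropyAtDelay(r, j, i, d))
        expect_identical(prof@slte[i, j, d + 1], slteAtDelay(r, j, i, d))
      }
    }
  }
})

test_that("a deterministic delayed copy gives peak at the true delay", {
  set.seed(5)
  T <- 1e5
  xj <- rbinom(T, 1, 0.5)
  xi <- c(rep(0, 3), xj[1:(T - 3)])
  r <- binSpikes(raster_to_sts(rbind(xi, xj)))
  p <- teProfile(r, source = 2, target = 1, dMax = 10)
  expect_equal(p@peakDelay, 3L)
  # TE at the copy delay equals H(i_t | i_{t-1}) for the same sequence
  t0 <- 4
  a <- xi[t0:T]; b <- xi[(t0 - 1):(T - 1)]
  h <- 0
  for (ai in 0:1) for (bi in 0:1) {
    nab <- sum(a == ai & b == bi); nb <- sum(b == bi)
    if (nab > 0) h <- h - nab / length(a) * log2(nab / nb)
  }
  expect_equal(p@peakTe, h, tolerance = 1e-12)
  expect_gt(p@peakTe, 0.9)
  expect_gte(p@sharpness, 0.999)  # off-peak mass is pure estimation noise
  expect_gt(p@eiBias, 0)
})

test_that("degenerate sources give zero TE and zero sharpness", {
  m <- rbind(rbinom(200, 1, 0.3), rep(0, 200))
  r <- binSpikes(raster_to_sts(m))
  p <- teProfile(r, source = 2, target = 1, dMax = 5)
  expect_true(all(p@te == 0))
  expect_equal(p@sharpness, 0)
  expect_equal(p@peakTe, 0)
})

test_that("plug-in bias of independent trains shrinks with length", {
  set.seed(21)
  te_at <- function(T) {
    m <- rbind(rbinom(T, 1, 0.1), rbinom(T, 1, 0.1))
    r <- binSpikes(raster_to_sts(m))
    mean(sapply(0:5, function(d) transferEntropyAtDelay(r, 2, 1, d)))
  }
  short <- mean(replicate(8, te_at(1000)))
  long <- mean(replicate(2, te_at(1e5)))
  expect_gt(short, 0)          # plug-in estimate is positively biased
  expect_lt(long, short / 5)   # and consistent: bias ~ 1/T
})

test_that("TE is asymmetric on directionally coupled pairs", {
  set.seed(31)
  T <- 5e4
  xj <- rbinom(T, 1, 0.2)
  xi <- ifelse(c(0, xj[-T]) == 1, rbinom(T, 1, 0.8), rbinom(T, 1, 0.02))
  r <- binSpikes(raster_to_sts(rbind(xi, xj)))
  fwd <- transferEntropyAtDelay(r, 2, 1, 1)
  bwd <- transferEntropyAtDelay(r, 1, 2, 1)
  expect_gt(fwd, 5 * bwd)
})

test_that("sharpness follows its printed definition", {
  te <- rep(0, 31); te[6] <- 0.4           # single mass at d = 5, tau 4
  expect_equal(sharpness(te, 5, tau = 4), 1)
  expect_equal(sharpness(rep(0.1, 31), 0, tau = 4), 5 / 31)
  expect_equal(sharpness(rep(0, 31), 0), 0)
  expect_error(sharpness(te, 5, tau = -1), "tau")
  # window is clipped at dMax
  te2 <- rep(0.1, 31)
  expect_equal(sharpness(te2, 29, tau = 4), 1)
})

test_that("rate normalization of peak TE behaves as the binary entropy", {
  expect_equal(teNormalized(0.5, 0.5), 0.5)
  expect_equal(teNormalized(0, 0.3), 0)
  expect_warning(v <- teNormalized(0.1, 1), "degenerate")
  expect_equal(v, 0)
  # capping at 1/nBins keeps the normalization finite as p -> 0
  v1 <- teNormalized(0.1, 1e-12, nBinsCap = 1e4)
  expect_equal(v1, teNormalized(0.1, 1e-4))
  expect_true(is.finite(v1))
})

test_that("SLTE sign separates engineered excitatory and inhibitory drive", {
  set.seed(41)
  T <- 1e5
  xj <- rbinom(T, 1, 0.05)
  jprev <- c(0, 0, xj[1:(T - 2)])
  exc <- ifelse(jprev == 1, rbinom(T, 1, 0.7), rbinom(T, 1, 0.05))
  inh <- ifelse(jprev == 1, rbinom(T, 1, 0.001), rbinom(T, 1, 0.15))
  iid1 <- rbinom(T, 1, 0.1)
  iid2 <- rbinom(T, 1, 0.1)
  r <- binSpikes(raster_to_sts(rbind(exc, inh, xj, iid1, iid2)))
  pe <- teProfile(r, source = 3, target = 1)
  pi_ <- teProfile(r, source = 3, target = 2)
  expect_equal(pe@peakDelay, 2L)
  expect_equal(pi_@peakDelay, 2L)
  expect_gt(pe@eiBias, 0)
  expect_lt(pi_@eiBias, 0)
  # independent pair: |SLTE| below the engineered couplings by far
  ind <- teProfile(r, source = 4, target = 5)
  expect_lt(abs(ind@eiBias), abs(pi_@eiBias) / 5)
})

test_that("profile summaries are consistent with their own curves", {
  set.seed(51)
  m <- random_raster(3, 2000, 0.1)
  r <- binSpikes(raster_to_sts(m))
  ps <- pairStats(teAllPairs(r, dMax = 12), tau = 4)
  prof <- teProfile(r, source = 2, target = 1, dMax = 12)
  row <- ps[ps$source == "n2" & ps$target == "n1", ]
  expect_equal(row$peak_te, max(prof@te))
  expect_equal(row$peak_delay, which.max(prof@te) - 1L)
  expect_equal(row$sharpness, sharpness(prof@te, row$peak_delay))
  expect_equal(row$ei_bias, prof@slte[row$peak_delay + 1L])
  expect_error(teProfile(r, 1, 1), "differ")
  expect_error(transferEntropyAtDelay(r, 2, 1, 2500), "shorter")
})
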