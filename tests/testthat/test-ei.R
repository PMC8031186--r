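test_that("feature construction drops the weakest tenth of outputs", {
  pairs <- data.frame(source = rep("a", 10),
                      target = paste0("t", 1:10),
                      ei_bias = c(rep(1, 9), -100),
                      te_nor = 10:1)  # the -100 bias has the lowest te_nor
  rates <- data.frame(neuron_id = c("a", "b"), rate_hz = c(2, 4),
                      p_spike = c(2e-3, 4e-3))
  fe <- neuronFeatures(pairs, rates, dropFrac = 0.10)
  # 10 outputs -> floor(0.9 * 10) = 9 retained; the worst-ranked is cut
  expect_equal(fe$sum_slte[fe$neuron_id == "a"], 9)
  expect_equal(fe$n_out[fe$neuron_id == "a"], 10)
  expect_false(fe$eligible[fe$neuron_id == "b"])
  expect_equal(fe$log10_fr[fe$neuron_id == "a"], log10(2))

  # dropFrac 0 keeps everything
  fe0 <- neuronFeatures(pairs, rates, dropFrac = 0)
  expect_equal(fe0$sum_slte[1], 9 - 100)
  # all-positive biases give a positive sum
  pairs$ei_bias <- abs(pairs$ei_bias)
  expect_gt(neuronFeatures(pairs, rates)$sum_slte[1], 0)
  expect_error(neuronFeatures(pairs, rates, dropFrac = 1), "dropFrac")
})

test_that("Ward clustering recovers well-separated classes and the sign rule", {
  set.seed(81)
  n1 <- 60; n2 <- 15
  fe <- data.frame(
    neuron_id = paste0("n", 1:(n1 + n2)),
    sum_slte = c(rnorm(n1, 2, 0.3), rnorm(n2, -1, 0.3)),
    log10_fr = c(rnorm(n1, 0.5, 0.2), rnorm(n2, 1.2, 0.2)),
    n_out = 5, eligible = TRUE)
  lab <- classifyEI(fe)
  expect_equal(unname(lab[1:n1]), rep("E", n1))
  expect_equal(unname(lab[(n1 + 1):(n1 + n2)]), rep("I", n2))

  # the cluster on the positive SLTE side is excitatory regardless of size
  fe2 <- fe
  fe2$sum_slte <- -fe2$sum_slte
  lab2 <- classifyEI(fe2)
  expect_equal(unname(lab2[1]), "I")
})

test_that("classification is invariant to axis rescaling and ordering", {
  set.seed(82)
  fe <- data.frame(neuron_id = paste0("n", 1:30),
                   sum_slte = c(rnorm(20, 1, 0.2), rnorm(10, -1, 0.2)),
                   log10_fr = rnorm(30), n_out = 3, eligible = TRUE)
  lab <- classifyEI(fe)
  fe_scaled <- fe
  fe_scaled$log10_fr <- -5 * fe_scaled$log10_fr + 2  # affine remap of axis 2
  expect_identical(classifyEI(fe_scaled), lab)
  perm <- sample(nrow(fe))
  expect_identical(classifyEI(fe[perm, ])[names(lab)], lab)
})

test_that("degenerate feature sets are handled explicitly", {
  fe2 <- data.frame(neuron_id = c("a", "b"), sum_slte = c(1, -1),
                    log10_fr = c(0, 0), n_out = 1, eligible = TRUE)
  lab <- classifyEI(fe2)   # two neurons: one cluster each, sign rule applies
  expect_equal(unname(lab), c("E", "I"))
  feq <- data.frame(neuron_id = c("a", "b", "c"), sum_slte = 1,
                    log10_fr = 2, n_out = 1, eligible = TRUE)
  expect_error(classifyEI(feq), "identical")
  fe1 <- fe2[1, ]
  expect_error(classifyEI(fe1), "two eligible")
  # ineligible neurons: rate-based nearest-neighbor fallback, else unlabeled
  fe2$log10_fr <- c(0, 2)
  fe3 <- rbind(fe2, data.frame(neuron_id = "z", sum_slte = 0, log10_fr = 1.9,
                               n_out = 0, eligible = FALSE))
  expect_equal(unname(classifyEI(fe3)["z"]), unname(classifyEI(fe3)["b"]))
  fe4 <- rbind(fe2, data.frame(neuron_id = "z", sum_slte = 0, log10_fr = NA,
                               n_out = 0, eligible = FALSE))
  expect_equal(unname(classifyEI(fe4)["z"]), "unlabeled")
})

test_that("accuracy scoring gives per-class recall and overall", {
  truth <- setNames(rep(c("E", "I"), c(90, 10)), paste0("n", 1:100))
  acc <- categorizationAccuracy(truth, truth)
  expect_equal(acc$acc_E, 100)
  expect_equal(acc$acc_I, 100)
  expect_equal(acc$overall, 100)
  allE <- setNames(rep("E", 100), names(truth))
  acc2 <- categorizationAccuracy(allE, truth)
  expect_equal(acc2$acc_E, 100)
  expect_equal(acc2$acc_I, 0)
  expect_equal(acc2$overall, 90)
  expect_error(categorizationAccuracy(setNames("E", "x"), truth), "share")
  # labels independent of truth land near the majority-class fraction
  set.seed(83)
  ov <- replicate(200, {
    categorizationAccuracy(setNames(sample(truth), names(truth)),
                           truth)$overall
  })
  expect_lt(abs(mean(ov) - (0.9^2 + 0.1^2) * 100), 2)
})
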