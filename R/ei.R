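#' Per-neuron classification features
#'
#' For each presynaptic neuron, its output pairs are ranked by
#' firing-rate-normalized peak TE (descending); the bottom `dropFrac`
#' fraction is discarded (retained count = `floor((1 - dropFrac) * n_out)`,
#' minimum 1) and the E-I biases (SLTE at the TE peak delay) of the rest are
#' summed. That sum, together with log10 firing rate, forms the
#' two-dimensional feature used for excitatory/inhibitory clustering.
#'
#' @param pairs [pairStats()] table (columns `source`, `ei_bias`, `te_nor`)
#' @param rates [firingRates()] table (columns `neuron_id`, `rate_hz`)
#' @param dropFrac fraction of weakest outputs to discard (default 0.10)
#' @return data.frame with `neuron_id`, `sum_slte`, `log10_fr`, `n_out`,
#'   `eligible` (FALSE for neurons with no output candidates)
#' @export
neuronFeatures <- function(pairs, rates, dropFrac = 0.10) {
  if (dropFrac < 0 || dropFrac >= 1) stop("dropFrac must be in [0, 1)")
  ids <- rates$neuron_id
  sum_slte <- n_out <- stats::setNames(numeric(length(ids)), ids)
  for (j in ids) {
    out <- pairs[pairs$source == j, , drop = FALSE]
    n_out[j] <- nrow(out)
    if (nrow(out) == 0) next
    keep <- max(floor((1 - dropFrac) * nrow(out)), 1L)
    ord <- order(out$te_nor, decreasing = TRUE)
    sum_slte[j] <- sum(out$ei_bias[ord[seq_len(keep)]])
  }
  data.frame(neuron_id = ids, sum_slte = unname(sum_slte),
             log10_fr = log10(pmax(rates$rate_hz, 1e-6)),
             n_out = unname(n_out), eligible = unname(n_out) > 0,
             stringsAsFactors = FALSE)
}

#' Excitatory/inhibitory classification by Ward clustering
#'
#' Standardizes the (sum SLTE, log10 firing rate) features per axis,
#' applies Ward variance-minimization agglomerative clustering
#' (`hclust(method = "ward.D2")` on Euclidean distances) cut at two
#' clusters, and labels the cluster with the larger mean SLTE sum
#' excitatory, the other inhibitory (Dale's principle gives the sign rule).
#' The z-scoring makes the result invariant to any affine rescaling of
#' either axis. Neurons without output candidates are excluded from
#' clustering; if they have a finite rate they inherit the label of the
#' nearest clustered neuron on the rate axis, otherwise `"unlabeled"`.
#'
#' @param features [neuronFeatures()] table
#' @return named character vector ("E", "I", or "unlabeled") per neuron
#' @export
classifyEI <- function(features) {
  el <- features[features$eligible, , drop = FALSE]
  if (nrow(el) < 2) stop("need at least two eligible neurons")
  X <- cbind(el$sum_slte, el$log10_fr)
  if (all(apply(X, 2, stats::sd) == 0))
    stop("all features identical: no cluster structure")
  Z <- apply(X, 2, function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  })
  hc <- stats::hclust(stats::dist(Z), method = "ward.D2")
  cl <- stats::cutree(hc, k = 2)
  m1 <- mean(el$sum_slte[cl == 1])
  m2 <- mean(el$sum_slte[cl == 2])
  lab_of_cluster <- if (m1 >= m2) c("E", "I") else c("I", "E")
  out <- stats::setNames(rep("unlabeled", nrow(features)),
                         features$neuron_id)
  out[el$neuron_id] <- lab_of_cluster[cl]
  # neurons without output candidates inherit the label of the nearest
  # clustered neuron along the firing-rate axis (when a rate is available)
  rest <- features[!features$eligible, , drop = FALSE]
  if (nrow(rest)) {
    ok <- is.finite(rest$log10_fr)
    for (k in which(ok)) {
      nn <- which.min(abs(el$log10_fr - rest$log10_fr[k]))
      out[rest$neuron_id[k]] <- lab_of_cluster[cl[nn]]
    }
  }
  out
}

#' Classification accuracy against ground truth
#'
#' Per-class recall (percentage of true excitatory neurons labeled
#' excitatory, and likewise for inhibitory) plus overall accuracy.
#'
#' @param pred named character labels ("E"/"I"; other values count as wrong)
#' @param truth named character ground-truth labels ("E"/"I")
#' @return list with `acc_E`, `acc_I`, `overall` (percent), and `n`
#' @export
categorizationAccuracy <- function(pred, truth) {
  common <- intersect(names(pred), names(truth))
  if (length(common) == 0) stop("prediction and truth share no neurons")
  p <- pred[common]; tr <- truth[common]
  accFor <- function(cls) {
    n <- sum(tr == cls)
    if (n == 0) return(NA_real_)
    100 * sum(p == cls & tr == cls) / n
  }
  list(acc_E = accFor("E"), acc_I = accFor("I"),
       overall = 100 * mean(p == tr), n = length(common))
}
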