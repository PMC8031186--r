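#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end workflow with validated defaults:
#' 1 ms bins, delay search window 0..30 ms, sharpness extension tau = 4 ms,
#' 100 jitter surrogates within +/- 10 ms, a 25 x 25 rejection grid with
#' RT threshold 0.34, a 10% weakest-output cut for the SLTE features, and a
#' 0.2 Hz firing-rate floor. A single root seed derives all per-stage seeds
#' (surrogate s uses `seed + s`).
#'
#' @param binMs,dMax,tau,nSurrogates,jitterWindow,gridN,rtThreshold,dropFrac,minRateHz
#'   stage parameters (see above)
#' @param seed root RNG seed
#' @param solverTimeLimit wall-clock budget (s) for the MFVS solver
#' @param classifyFvs also run the critical/intermittent/redundant
#'   classification (two exact re-solves per cycle node)
#' @return validated config (class `PipelineConfig`)
#' @export
pipelineConfig <- function(binMs = 1, dMax = 30, tau = 4, nSurrogates = 100,
                           jitterWindow = 10, gridN = 25, rtThreshold = 0.34,
                           dropFrac = 0.10, minRateHz = 0.2, seed = 1,
                           solverTimeLimit = 60, classifyFvs = FALSE) {
  stopifnot(binMs > 0, dMax >= 1, tau >= 0, nSurrogates >= 1,
            jitterWindow >= 1, gridN >= 2,
            rtThreshold >= 0, rtThreshold <= 1,
            dropFrac >= 0, dropFrac < 1, minRateHz >= 0,
            solverTimeLimit > 0)
  structure(list(binMs = binMs, dMax = dMax, tau = tau,
                 nSurrogates = nSurrogates, jitterWindow = jitterWindow,
                 gridN = gridN, rtThreshold = rtThreshold,
                 dropFrac = dropFrac, minRateHz = minRateHz,
                 seed = as.integer(seed),
                 solverTimeLimit = solverTimeLimit,
                 classifyFvs = classifyFvs),
            class = "PipelineConfig")
}

#' Run the full analysis pipeline
#'
#' Executes the mandated stage order: rate filtering, binning, all-pairs
#' TE/SLTE profiling, E/I classification (which must precede connection
#' selection, since surrogate comparisons are made separately per connection
#' category), four-category connection selection, network assembly, topology
#' metrics (degrees, coreness, log-normality of rates and strengths), and
#' minimum feedback vertex set analysis. Fully reproducible from the config
#' seed.
#'
#' @param spikes a [SpikeTrainSet-class]
#' @param cfg a [pipelineConfig()] object
#' @param verbose print stage progress
#' @return a `spikeTEBundle` list: `config`, `labels`, `features`, `rates`,
#'   `pairs`, `network`, `maps`, `metrics`, `fvs`, `fvsReport`
#' @export
runPipeline <- function(spikes, cfg = pipelineConfig(), verbose = FALSE) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  say <- function(...) if (verbose) message("[spikeTE] ", ...)

  say("filtering neurons below ", cfg$minRateHz, " Hz")
  sp <- filterLowRate(spikes, cfg$minRateHz)
  if (nNeurons(sp) < 3) stop("stage filter: fewer than 3 neurons survive")

  say("binning at ", cfg$binMs, " ms")
  r <- binSpikes(sp, cfg$binMs)
  rates <- firingRates(r)

  say("all-pairs TE/SLTE profiles (d = 0..", cfg$dMax, ")")
  prof <- teAllPairs(r, dMax = cfg$dMax)
  pairs <- pairStats(prof, tau = cfg$tau)

  say("E/I classification")
  feats <- neuronFeatures(pairs, rates, dropFrac = cfg$dropFrac)
  labels <- classifyEI(feats)

  say("connection selection (", cfg$nSurrogates, " surrogates x 4 categories)")
  asm <- assembleNetwork(r, labels, realStats = pairs,
                         nSurrogates = cfg$nSurrogates,
                         windowBins = cfg$jitterWindow, dMax = cfg$dMax,
                         tau = cfg$tau, gridN = cfg$gridN,
                         rtThreshold = cfg$rtThreshold, seed = cfg$seed,
                         details = TRUE)
  net <- asm$network

  say("topology metrics")
  deg <- degreeStats(net)
  kc <- kcoreCentrality(net)
  lnRate <- tryCatch(lognormalTest(rates$rate_hz[rates$rate_hz > 0]),
                     error = function(e) NULL)
  w <- igraph::E(asIgraph(net))$weight
  lnW <- tryCatch(lognormalTest(w[w > 0]), error = function(e) NULL)

  say("minimum feedback vertex set")
  fv <- mfvs(net, solverTimeLimit = cfg$solverTimeLimit)
  if (cfg$classifyFvs && fv@status == "optimal")
    fv <- classifyFVSNodes(net, fv,
                           perNodeTimeLimit = cfg$solverTimeLimit)
  fvRep <- if (fv@status == "optimal")
    fvsGroupReport(net, fv, kc) else NULL

  structure(list(config = cfg, labels = labels, features = feats,
                 rates = rates, pairs = asm$pairs, network = net,
                 maps = asm$maps,
                 metrics = list(degrees = deg, kcore = kc,
                                lognormal_rate = lnRate,
                                lognormal_strength = lnW),
                 fvs = fv, fvsReport = fvRep),
            class = "spikeTEBundle")
}

#' Human-readable pipeline report
#'
#' Summary tables mirroring the standard panels: E/I counts and inhibitory
#' fraction, firing-rate and strength distributions with Anderson-Darling
#' statistics, degree summaries, mean coreness by label, FVS ratios and
#' FVS/k-core overlap, and (when ground truth is attached to the spike set)
#' the E/I confusion matrix.
#'
#' @param bundle output of [runPipeline()]
#' @param truth optional named ground-truth labels for a confusion matrix
#' @return character vector of report lines (also printed invisibly)
#' @export
makeReport <- function(bundle, truth = NULL) {
  stopifnot(inherits(bundle, "spikeTEBundle"))
  L <- character(0)
  add <- function(...) L <<- c(L, sprintf(...))
  lab <- bundle$labels
  nE <- sum(lab == "E"); nI <- sum(lab == "I")
  add("Neurons: %d (E %d, I %d, unlabeled %d); inhibitory fraction %.3f",
      length(lab), nE, nI, sum(lab == "unlabeled"),
      if (nE + nI > 0) nI / (nE + nI) else NA)
  g <- asIgraph(bundle$network)
  add("Edges accepted: %d (density %.4f)", igraph::ecount(g),
      igraph::edge_density(g))
  if (!is.null(bundle$metrics$lognormal_rate))
    with(bundle$metrics$lognormal_rate,
         add("Firing rates: log-normal AD = %.3f, p = %.3g (mu %.2f, sigma %.2f)",
             statistic, p_value, mu, sigma))
  if (!is.null(bundle$metrics$lognormal_strength))
    with(bundle$metrics$lognormal_strength,
         add("Strengths: log-normal AD = %.3f, p = %.3g", statistic,
             p_value))
  kc <- bundle$metrics$kcore
  for (cl in c("E", "I")) {
    sel <- names(kc) %in% names(lab)[lab == cl]
    if (any(sel)) add("Mean k-core (%s): %.3f", cl, mean(kc[sel]))
  }
  if (bundle$fvs@status == "optimal") {
    add("MFVS size: %d", bundle$fvs@size)
    rep_ <- bundle$fvsReport
    add("FVS ratio E: %.3f, I: %.3f", rep_$ratio_E, rep_$ratio_I)
    add("FVS in max k-core: %.1f%% of FVS, %.1f%% of max core",
        100 * rep_$overlap[1], 100 * rep_$overlap[2])
  } else add("MFVS: %s", bundle$fvs@status)
  if (!is.null(truth)) {
    acc <- categorizationAccuracy(bundle$labels, truth)
    add("E/I accuracy vs truth: E %.1f%%, I %.1f%%, overall %.1f%%",
        acc$acc_E, acc$acc_I, acc$overall)
  }
  cat(L, sep = "\n")
  invisible(L)
}
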