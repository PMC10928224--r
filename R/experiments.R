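#' Configuration of a Gestalt experiment
#'
#' Bundles the stimulus series, trial budget, neuron-selection size and all
#' model parameter blocks for one end-to-end experiment. Defaults follow the
#' replication protocol: 100 trials per stimulus, group selections of 4
#' neurons per segment for proximity and 5 for similarity/continuity,
#' signal-to-noise ratio 0.4, 40 Hz Poisson drive, 20 x 20 grid.
#'
#' @param principle "proximity", "similarity" or "continuity"
#' @param levels level series; defaults to the principle's full series
#' @param nTrials trials per stimulus
#' @param kPerSegment neurons sampled per segment for group Rsync
#' @param selectionsPerTrial independent random selections averaged per
#'   trial measurement (selection sampling noise reduction; the underlying
#'   quantity is selection-insensitive)
#' @param gridSize pixel grid side
#' @param snr background noise amplitude ratio
#' @param rateHz Poisson rate (Hz)
#' @param seed base seed of the experiment
#' @param timescaleMs activation-kernel timescale (ms)
#' @param pairwise also accumulate pairwise Rsync tables (needed for the
#'   connectivity--synchrony correlation)
#' @param jitter also measure every group Rsync on a spike-time-jittered
#'   copy of each record (the temporal-structure control)
#' @param Slat,Sext,Sd,Sa connectivity / input scale overrides
#' @param izh,syn,sim parameter blocks (Sext is injected into \code{syn})
#' @return a classed config list
#' @export
experimentConfig <- function(principle,
                             levels = defaultLevels(principle),
                             nTrials = 100,
                             kPerSegment = if (principle == "proximity") 4L else 5L,
                             selectionsPerTrial = 8L,
                             gridSize = 20, snr = 0.4, rateHz = 40,
                             seed = 1, timescaleMs = 3,
                             pairwise = FALSE, jitter = FALSE,
                             Sd = defaultScales()$Sd,
                             Sa = defaultScales()$Sa,
                             Slat = defaultScales()$Slat,
                             Sext = defaultScales()$Sext,
                             izh = izhikevichParams(),
                             syn = synapseParams(Sext = Sext),
                             sim = simParams()) {
  stopifnot(principle %in% c("proximity", "similarity", "continuity"))
  if (!all(levels %in% defaultLevels(principle)))
    stop("levels outside the valid series for ", principle)
  structure(list(principle = principle, levels = levels, nTrials = nTrials,
                 kPerSegment = as.integer(kPerSegment),
                 selectionsPerTrial = as.integer(selectionsPerTrial),
                 gridSize = gridSize,
                 snr = snr, rateHz = rateHz, seed = seed,
                 timescaleMs = timescaleMs, pairwise = pairwise,
                 jitter = jitter, Sd = Sd, Sa = Sa, Slat = Slat,
                 izh = izh, syn = syn, sim = sim),
            class = c("ExperimentConfig", "list"))
}

# segment pairs measured per trial: proximity/similarity pool segments 1+2;
# continuity compares same-line pairs (1,3), (2,4) with different-line
# pairs (1,2), (3,4)
measurementPlan <- function(principle) {
  if (principle == "continuity")
    list(list(segments = c(1, 3), pairType = "same"),
         list(segments = c(2, 4), pairType = "same"),
         list(segments = c(1, 2), pairType = "different"),
         list(segments = c(3, 4), pairType = "different"))
  else
    list(list(segments = c(1, 2), pairType = "1+2"))
}

#' Run one Gestalt experiment end to end
#'
#' For every level of the configured series: generates the stimulus, then
#' for each trial draws a fresh noise field and Poisson encoding, simulates
#' the network, and measures group Rsync for the principle's segment plan
#' (optionally also on a jittered copy, and optionally the full pairwise
#' Rsync tables). Failed or runaway trials are excluded from the
#' measurement table and counted. The same lateral connectivity is shared
#' by all levels.
#'
#' @param config an \code{\link{experimentConfig}}
#' @return object of class \code{GestaltExperiment}: list with
#'   \code{measurements} (one row per trial and segment pair: level,
#'   trial, pairType, value, valueJitter), \code{pairwise} (mean pairwise
#'   Rsync per neuron pair and level, when requested), \code{tests}
#'   (\code{\link{nonparametricTests}} output), \code{excluded}, and the
#'   \code{config}
#' @export
runGestaltExperiment <- function(config) {
  stims <- generateStimulusSeries(config$principle, config$levels,
                                  config$gridSize)
  conn <- buildConnectivity(config$gridSize, Sd = config$Sd, Sa = config$Sa,
                            Slat = config$Slat)
  plan <- measurementPlan(config$principle)
  meas <- list()
  pairAcc <- list()
  excluded <- 0L
  for (li in seq_along(stims)) {
    stim <- stims[[li]]
    level <- config$levels[li]
    driven <- drivenNeurons(stim)
    # per-level, per-trial seed streams derived from the base seed
    levelSeed <- (as.numeric(config$seed) * 1009 + li * 7919) %% 2147483646 + 1
    seeds <- trialSeeds(levelSeed, config$nTrials)
    psum <- NULL; pn <- 0L
    for (t in seq_len(config$nTrials)) {
      rec <- simulateStimulusTrial(stim, conn, seedR = seeds$r[t],
                                   seedCpp = seeds$cpp[t], snr = config$snr,
                                   rateHz = config$rateHz, izh = config$izh,
                                   syn = config$syn, sim = config$sim)
      if (rec@runaway) { excluded <- excluded + 1L; next }
      jit <- if (config$jitter) jitterNull(rec, seed = seeds$r[t] + 1L)
      # activation traces of all driven neurons, once per trial
      traces <- activationTrace(rec@spikes[driven$neuron, , drop = FALSE],
                                timescaleMs = config$timescaleMs,
                                binMs = rec@binMs)
      tracesJ <- if (config$jitter)
        activationTrace(jit@spikes[driven$neuron, , drop = FALSE],
                        timescaleMs = config$timescaleMs, binMs = jit@binMs)
      for (pi in seq_along(plan)) {
        # the group measure is averaged over independent random selections
        # of k neurons per segment; the selection is an estimator choice,
        # not part of the physics, and averaging removes its sampling noise
        set.seed(seeds$cpp[t] + pi)
        vals <- numeric(config$selectionsPerTrial)
        valsJ <- numeric(config$selectionsPerTrial)
        for (s in seq_len(config$selectionsPerTrial)) {
          rows <- unlist(lapply(plan[[pi]]$segments, function(sg) {
            pool <- which(driven$segment == sg)
            if (length(pool) < config$kPerSegment)
              stop(sprintf("segment %s has only %d driven neurons, %d requested",
                           sg, length(pool), config$kPerSegment))
            sample(pool, config$kPerSegment)
          }))
          vals[s] <- rsync(traces[rows, , drop = FALSE])
          if (config$jitter) valsJ[s] <- rsync(tracesJ[rows, , drop = FALSE])
        }
        meas[[length(meas) + 1L]] <- data.frame(
          principle = config$principle, level = level,
          pairType = plan[[pi]]$pairType, trial = t, value = mean(vals),
          valueJitter = if (config$jitter) mean(valsJ) else NA_real_)
      }
      if (config$pairwise) {
        pw <- pairwiseTables(rec, stim, config, driven)
        if (is.null(psum)) psum <- pw else psum$value <- psum$value + pw$value
        pn <- pn + 1L
      }
    }
    if (config$pairwise && pn > 0L) {
      psum$value <- psum$value / pn
      psum$level <- level
      pairAcc[[length(pairAcc) + 1L]] <- psum
    }
  }
  measurements <- do.call(rbind, meas)
  pairwise <- if (length(pairAcc)) do.call(rbind, pairAcc)
  tests <- experimentTests(config$principle, measurements)
  structure(list(measurements = measurements, pairwise = pairwise,
                 tests = tests, excluded = excluded, config = config),
            class = "GestaltExperiment")
}

# mean pairwise Rsync per neuron pair for one trial, over the pairings the
# principle calls for (within both segments and between segments;
# continuity: within-line 1-3 and cross-line 1-2, 3-4)
pairwiseTables <- function(rec, stim, config, driven) {
  pairsOf <- function(sa, sb, mode) {
    pw <- avgPairwiseRsync(rec, stim, sa, sb,
                           timescaleMs = config$timescaleMs, driven = driven)
    if (nrow(pw$pairs))
      cbind(pw$pairs, mode = mode, segA = sa, segB = sb)
  }
  combos <- if (config$principle == "continuity")
    list(c(1, 3, "within-line"), c(1, 2, "between-line"),
         c(3, 4, "between-line"))
  else
    list(c(1, 1, "within"), c(2, 2, "within"), c(1, 2, "between"))
  out <- do.call(rbind, lapply(combos, function(x)
    pairsOf(as.numeric(x[1]), as.numeric(x[2]), x[3])))
  out[order(out$mode, out$i, out$j), , drop = FALSE]
}

# the statistical comparisons of one experiment
experimentTests <- function(principle, measurements) {
  if (principle == "continuity") {
    res <- lapply(sort(unique(measurements$level)), function(lv) {
      d <- measurements[measurements$level == lv, ]
      w <- nonparametricTests(split(d$value, d$pairType))
      cbind(level = lv, w)
    })
    do.call(rbind, res)
  } else {
    groups <- split(measurements$value, measurements$level)
    lv <- as.numeric(names(groups))
    ext <- nonparametricTests(groups[as.character(range(lv))])
    out <- cbind(level = NA_real_, ext)
    if (length(groups) > 2) {
      multi <- nonparametricTests(groups)
      out <- rbind(cbind(level = NA_real_, multi), out)
    }
    out
  }
}

#' Nonparametric group comparisons
#'
#' Two groups: Wilcoxon rank-sum (Mann--Whitney; set
#' \code{paired = TRUE} for the signed-rank variant). Three or more groups:
#' Kruskal--Wallis with epsilon-squared and eta-squared effect sizes,
#' followed by the Dunn post-hoc z tests on the joint ranks with Bonferroni
#' adjustment. Ties are handled by the standard tie corrections. A single
#' group is returned untested with a note.
#'
#' @param groups named list of numeric vectors
#' @param paired use the signed-rank variant for two groups
#' @return data.frame with one row per test: test, group1, group2,
#'   statistic, p, pAdjusted, effectSize, effectType, note
#' @export
nonparametricTests <- function(groups, paired = FALSE) {
  stopifnot(is.list(groups), all(vapply(groups, length, 1L) > 0))
  nms <- names(groups)
  if (length(groups) == 1L)
    return(data.frame(test = "none", group1 = nms[1], group2 = NA,
                      statistic = NA_real_, p = NA_real_,
                      pAdjusted = NA_real_, effectSize = NA_real_,
                      effectType = NA_character_,
                      note = "single group: comparison skipped"))
  if (length(groups) == 2L) {
    w <- stats::wilcox.test(groups[[1]], groups[[2]], paired = paired,
                            exact = FALSE)
    n1 <- length(groups[[1]]); n2 <- length(groups[[2]])
    # rank-biserial correlation as the two-group effect size
    eff <- if (!paired) unname(1 - 2 * w$statistic / (n1 * n2)) else NA_real_
    return(data.frame(test = if (paired) "wilcoxon_signed_rank"
                             else "wilcoxon_rank_sum",
                      group1 = nms[1], group2 = nms[2],
                      statistic = unname(w$statistic), p = w$p.value,
                      pAdjusted = w$p.value, effectSize = eff,
                      effectType = "rank_biserial", note = ""))
  }
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(nms, vapply(groups, length, 1L)), levels = nms)
  kw <- stats::kruskal.test(values, labels)
  n <- length(values); k <- length(groups)
  H <- unname(kw$statistic)
  out <- data.frame(test = "kruskal_wallis", group1 = NA, group2 = NA,
                    statistic = H, p = kw$p.value, pAdjusted = kw$p.value,
                    effectSize = H / (n - 1), effectType = "epsilon_squared",
                    note = sprintf("eta_squared=%.4f",
                                   (H - k + 1) / (n - k)))
  rbind(out, dunnTest(values, labels))
}

#' Dunn post-hoc test with Bonferroni adjustment
#'
#' Pairwise z statistics on the joint ranks after a Kruskal--Wallis test,
#' \deqn{z = (\bar R_a - \bar R_b) / \sqrt{(N(N+1)/12 - C)\,(1/n_a + 1/n_b)}}
#' with the tie correction \eqn{C = \sum (t^3 - t) / (12 (N - 1))};
#' two-sided p values, Bonferroni-adjusted over all pairs
#' (\eqn{p_{adj} = \min(1, m\,p)}).
#'
#' @param values numeric vector of all observations
#' @param labels factor of group labels, same length
#' @return data.frame with one row per group pair
#' @export
dunnTest <- function(values, labels) {
  labels <- droplevels(as.factor(labels))
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  C <- sum(ties^3 - ties) / (12 * (N - 1))
  meanR <- tapply(r, labels, mean)
  ns <- tapply(r, labels, length)
  nms <- levels(labels)
  cmb <- utils::combn(nms, 2)
  m <- ncol(cmb)
  res <- lapply(seq_len(m), function(i) {
    a <- cmb[1, i]; b <- cmb[2, i]
    z <- (meanR[[a]] - meanR[[b]]) /
      sqrt((N * (N + 1) / 12 - C) * (1 / ns[[a]] + 1 / ns[[b]]))
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(test = "dunn_bonferroni", group1 = a, group2 = b,
               statistic = z, p = p, pAdjusted = min(1, m * p),
               effectSize = NA_real_, effectType = NA_character_,
               note = "")
  })
  do.call(rbind, res)
}

#' Correlation between pairwise synchrony and connectivity strength
#'
#' Pearson correlation between the mean pairwise Rsync of neuron pairs and
#' their lateral weight \eqn{W^{lat}_{ij}}, over all measured pairs of an
#' experiment (and per level).
#'
#' @param pairTable the \code{pairwise} table of a
#'   \code{\link{runGestaltExperiment}} result (columns i, j, value, level)
#' @param conn the experiment's \code{\link{LateralConnectivity}}
#' @return data.frame: one row per level plus one pooled row, with columns
#'   level, r, p, n
#' @export
correlateConnectivitySynchrony <- function(pairTable, conn) {
  stopifnot(nrow(pairTable) > 0)
  one <- function(d, lv) {
    w <- connWeight(conn, d$i, d$j)
    if (stats::sd(d$value) == 0 || stats::sd(w) == 0)
      stop("undefined correlation: constant input")
    ct <- stats::cor.test(d$value, w, method = "pearson")
    data.frame(level = lv, r = unname(ct$estimate), p = ct$p.value,
               n = nrow(d))
  }
  perLevel <- do.call(rbind, lapply(split(pairTable, pairTable$level),
    function(d) one(d, d$level[1])))
  rbind(perLevel, one(pairTable, NA_real_))
}

#' @rdname runGestaltExperiment
#' @param ... overrides passed to \code{\link{experimentConfig}}
#' @export
runProximityExperiment <- function(...)
  runGestaltExperiment(experimentConfig("proximity", ...))

#' @rdname runGestaltExperiment
#' @export
runSimilarityExperiment <- function(...)
  runGestaltExperiment(experimentConfig("similarity", ...))

#' @rdname runGestaltExperiment
#' @export
runContinuityExperiment <- function(...)
  runGestaltExperiment(experimentConfig("continuity", ...))

#' Pairwise (within vs between segment) synchrony analysis
#'
#' Convenience wrapper: runs the experiment with pairwise accumulation and
#' summarizes mean pairwise Rsync per level and pairing mode, the
#' within-vs-between contrast, and the connectivity correlation.
#'
#' @param config an \code{\link{experimentConfig}} (its \code{pairwise}
#'   flag is forced on)
#' @return list with \code{experiment}, \code{summary} (level, mode, mean
#'   value) and \code{correlation}
#' @export
runPairwiseAnalysis <- function(config) {
  config$pairwise <- TRUE
  exp <- runGestaltExperiment(config)
  conn <- buildConnectivity(config$gridSize, Sd = config$Sd, Sa = config$Sa,
                            Slat = config$Slat)
  smry <- stats::aggregate(value ~ level + mode, exp$pairwise, mean)
  corr <- correlateConnectivitySynchrony(exp$pairwise, conn)
  list(experiment = exp, summary = smry, correlation = corr)
}

#' Write and re-read experiment measurements as tidy CSV
#'
#' One row per trial measurement; round-trips losslessly (numeric values
#' written at full precision).
#'
#' @param experiment a \code{GestaltExperiment}
#' @param path CSV path
#' @export
writeMeasurementsCSV <- function(experiment, path) {
  d <- experiment$measurements
  d$seed <- experiment$config$seed
  utils::write.csv(format(d, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeMeasurementsCSV
#' @export
readMeasurementsCSV <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @export
print.GestaltExperiment <- function(x, ...) {
  m <- x$measurements
  cat(sprintf("GestaltExperiment (%s): %d levels x %d trials, %d measurements%s\n",
              x$config$principle, length(x$config$levels), x$config$nTrials,
              nrow(m),
              if (x$excluded) sprintf(" (%d trials excluded)", x$excluded)
              else ""))
  agg <- stats::aggregate(value ~ level + pairType, m, stats::median)
  names(agg)[3] <- "medianRsync"
  print(agg, row.names = FALSE)
  invisible(x)
}
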