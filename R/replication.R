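#' Reduced-trial replication of the three Gestalt experiments
#'
#' Runs the extreme-condition protocol at a configurable trial budget:
#' proximity gaps 0 and 4, similarity angle differences 0 and 90,
#' continuity angle differences 23 and 90 (same-line vs different-line
#' pairs), each with jittered controls and pairwise Rsync accumulation,
#' plus a lateral-ablation run (\code{Slat = 0}) of the proximity pair.
#' This is the protocol behind the headline numbers: condition medians,
#' extreme-pair rank-sum tests, jitter controls, and the
#' connectivity--synchrony Pearson correlations.
#'
#' @param seed base seed; all randomness (stimulus noise, Poisson
#'   encoding, integrator noise, neuron selection, jitter) derives from it
#' @param nTrials trials per stimulus condition
#' @param ablation also run the \code{Slat = 0} control
#' @param fullLevels run the full level series instead of the extremes
#'   (slower; used for the complete dose-response picture)
#' @return list of \code{GestaltExperiment} objects (\code{proximity},
#'   \code{similarity}, \code{continuity}, optionally \code{ablation}) plus
#'   \code{summary}, a data.frame of condition medians
#' @export
runReplication <- function(seed = 1, nTrials = 20, ablation = TRUE,
                           fullLevels = FALSE) {
  lv <- function(p, extremes) if (fullLevels) defaultLevels(p) else extremes
  exps <- list(
    proximity = runGestaltExperiment(experimentConfig(
      "proximity", levels = lv("proximity", c(0, 4)), nTrials = nTrials,
      seed = seed, jitter = TRUE, pairwise = TRUE)),
    similarity = runGestaltExperiment(experimentConfig(
      "similarity", levels = lv("similarity", c(0, 90)), nTrials = nTrials,
      seed = seed + 1, jitter = TRUE, pairwise = TRUE)),
    continuity = runGestaltExperiment(experimentConfig(
      "continuity", levels = lv("continuity", c(23, 90)), nTrials = nTrials,
      seed = seed + 2, jitter = TRUE, pairwise = TRUE)))
  if (ablation)
    exps$ablation <- runGestaltExperiment(experimentConfig(
      "proximity", levels = lv("proximity", c(0, 4)), nTrials = nTrials,
      seed = seed + 3, Slat = 0))
  smry <- do.call(rbind, lapply(names(exps), function(nm) {
    m <- exps[[nm]]$measurements
    agg <- stats::aggregate(value ~ level + pairType, m, stats::median)
    data.frame(experiment = nm, level = agg$level, pairType = agg$pairType,
               medianRsync = agg$value)
  }))
  exps$summary <- smry
  exps
}

#' Headline quantities of a replication run
#'
#' Extracts the condition medians, the extreme-pair rank-sum p values, the
#' continuity same-vs-different p values, the jitter-control p values and
#' the per-experiment connectivity--synchrony Pearson correlations from a
#' \code{\link{runReplication}} result.
#'
#' @param rep result of \code{\link{runReplication}}
#' @return named list of scalars
#' @export
replicationHeadline <- function(rep) {
  med <- function(exp, level, pairType = NULL) {
    m <- exp$measurements
    m <- m[m$level == level, ]
    if (!is.null(pairType)) m <- m[m$pairType == pairType, ]
    stats::median(m$value)
  }
  rankP <- function(exp) {
    w <- exp$tests[exp$tests$test == "wilcoxon_rank_sum", ]
    w$p[nrow(w)]  # the extreme-pair comparison
  }
  contP <- function(exp, level) {
    w <- exp$tests[exp$tests$test == "wilcoxon_rank_sum" &
                   exp$tests$level == level, ]
    w$p[1]
  }
  jitterP <- function(exp) {
    m <- exp$measurements
    if (exp$config$principle == "continuity") {
      sapply(unique(m$level), function(lv) {
        d <- m[m$level == lv, ]
        stats::wilcox.test(d$valueJitter[d$pairType == "same"],
                           d$valueJitter[d$pairType == "different"],
                           exact = FALSE)$p.value
      })
    } else {
      lv <- range(m$level)
      stats::wilcox.test(m$valueJitter[m$level == lv[1]],
                         m$valueJitter[m$level == lv[2]],
                         exact = FALSE)$p.value
    }
  }
  pearson <- function(exp) {
    conn <- buildConnectivity(exp$config$gridSize, Sd = exp$config$Sd,
                              Sa = exp$config$Sa, Slat = exp$config$Slat)
    res <- correlateConnectivitySynchrony(exp$pairwise, conn)
    res$r[which(!is.na(res$level))]  # per-stimulus correlations
  }
  ablationP <- if (!is.null(rep$ablation)) {
    w <- rep$ablation$tests[rep$ablation$tests$test == "wilcoxon_rank_sum", ]
    w$p[nrow(w)]
  } else NA_real_
  pear <- lapply(rep[c("proximity", "similarity", "continuity")], pearson)
  list(
    proximity_median_gap0 = med(rep$proximity, 0),
    proximity_median_gap4 = med(rep$proximity, 4),
    similarity_median_0deg = med(rep$similarity, 0),
    similarity_median_90deg = med(rep$similarity, 90),
    continuity_median_same_23deg = med(rep$continuity, 23, "same"),
    continuity_median_different_23deg = med(rep$continuity, 23, "different"),
    continuity_median_same_90deg = med(rep$continuity, 90, "same"),
    continuity_median_different_90deg = med(rep$continuity, 90, "different"),
    proximity_rank_sum_p = rankP(rep$proximity),
    similarity_rank_sum_p = rankP(rep$similarity),
    continuity_same_vs_different_p_23deg = contP(rep$continuity, 23),
    continuity_same_vs_different_p_90deg = contP(rep$continuity, 90),
    jitter_p = c(proximity = jitterP(rep$proximity),
                 similarity = jitterP(rep$similarity),
                 continuity = unname(jitterP(rep$continuity))),
    ablation_p = ablationP,
    pearson_r = pear,
    pearson_r_max = max(unlist(pear)))
}
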