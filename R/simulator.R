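#' Simulate one trial of the network
#'
#' Forward-Euler integration of the pulse-coupled, fully excitatory
#' Izhikevich network at \code{dtMs} resolution under external Poisson
#' drive, with exact exponential updates of the receptor kinetics
#' (the transmitter pulse is piecewise constant on the step grid). Spikes
#' are recorded on the \code{binMs} grid and the initial transient is
#' excluded from the returned record. A population mean rate above
#' \code{runawayRateHz} sets the runaway flag on the record instead of
#' raising an error.
#'
#' @param extInput an \code{\link{ExternalSpikeInput}} covering transient
#'   plus analysis window
#' @param conn a \code{\link{LateralConnectivity}} for the same grid
#' @param izh \code{\link{izhikevichParams}}
#' @param syn \code{\link{synapseParams}}
#' @param sim \code{\link{simParams}}
#' @param seed integer seed for the integrator's voltage-noise RNG
#' @return a \code{\link{SpikeRecord}}
#' @export
runTrial <- function(extInput, conn, izh = izhikevichParams(),
                     syn = synapseParams(), sim = simParams(), seed = 1) {
  P <- prod(conn@gridDim)
  K <- length(conn@orientations)
  N <- P * K
  stopifnot(nrow(extInput@spikes) == N,
            abs(extInput@binMs - sim$binMs) < 1e-12)
  pixOf <- rep(seq_len(P), times = K) - 1L
  chOf <- rep(seq_len(K), each = P) - 1L
  res <- .run_trial_cpp(extInput@spikes, conn@distanceWeights,
                        conn@angleWeights, pixOf, chOf,
                        conn@Sd, conn@Sa, conn@Slat, syn$Sext,
                        izh$a, izh$b, izh$c, izh$d, izh$vThresh, izh$Seps,
                        syn$Erev, syn$alpha, syn$beta, syn$tauMs,
                        sim$dtMs, sim$transientMs, sim$durationMs, sim$binMs,
                        sim$runawayRateHz, as.numeric(seed))
  new("SpikeRecord", spikes = res$spikes, binMs = sim$binMs,
      t0Ms = sim$transientMs, durationMs = sim$durationMs,
      gridDim = conn@gridDim, nChannels = as.integer(K),
      rates = as.numeric(res$rates), runaway = isTRUE(res$runaway),
      seed = as.numeric(seed))
}

#' Receptor open-fraction trajectory for a given spike schedule
#'
#' Runs the simulator's receptor update (exact piecewise-exponential
#' integration of \eqn{\dot r = \alpha [T] (1-r) - \beta r} with a unit
#' transmitter pulse of duration \code{tauMs} after each spike) for a
#' single synapse. Used to validate the synapse kinetics against the
#' closed-form solution.
#'
#' @param spikeTimesMs vector of presynaptic spike times (ms)
#' @param durationMs trajectory length (ms)
#' @param syn \code{\link{synapseParams}}
#' @param dtMs integration step (ms)
#' @return numeric vector: r at the end of each step
#' @export
receptorTrace <- function(spikeTimesMs, durationMs, syn = synapseParams(),
                          dtMs = 0.005) {
  nSteps <- round(durationMs / dtMs)
  steps <- as.integer(round(spikeTimesMs / dtMs))
  .receptor_trace_cpp(steps, nSteps, dtMs, syn$alpha, syn$beta, syn$tauMs)
}

#' Reference (naive) trial integrator
#'
#' Plain R re-implementation of \code{\link{runTrial}} that materializes the
#' full weight matrix and performs the dense lateral sum at every step.
#' Semantically identical to the optimized integrator when voltage noise is
#' disabled (\code{Seps = 0}; the two use different RNG streams), and only
#' practical for small grids and short runs. Kept as an independent check
#' of the factored-connectivity fast path.
#'
#' @inheritParams runTrial
#' @param W full N x N lateral weight matrix (zero diagonal)
#' @return a \code{\link{SpikeRecord}}-like list with elements
#'   \code{spikes}, \code{rates}
#' @export
runTrialReference <- function(extInput, W, izh = izhikevichParams(Seps = 0),
                              syn = synapseParams(), sim = simParams()) {
  N <- nrow(W)
  dt <- sim$dtMs
  stepsPerBin <- round(sim$binMs / dt)
  totalBins <- round((sim$transientMs + sim$durationMs) / sim$binMs)
  transientBins <- round(sim$transientMs / sim$binMs)
  pulseSteps <- max(1, round(syn$tauMs / dt))
  edec <- exp(-syn$beta * dt)
  epul <- exp(-(syn$alpha + syn$beta) * dt)
  rinf <- syn$alpha / (syn$alpha + syn$beta)
  v <- rep(-65, N); u <- izh$b * v
  rl <- numeric(N); re <- numeric(N)
  pl <- integer(N); pe <- integer(N)
  spikes <- matrix(FALSE, N, totalBins - transientBins)
  ext <- extInput@spikes
  for (step in seq_len(totalBins * stepsPerBin) - 1L) {
    bin <- step %/% stepsPerBin
    if (step %% stepsPerBin == 0L) pe[ext[, bin + 1L]] <- pulseSteps
    gLat <- as.numeric(W %*% rl)
    I <- (v - syn$Erev) * gLat + (v - syn$Erev) * re * syn$Sext
    eps <- if (izh$Seps > 0) (stats::runif(N) - 0.5) * izh$Seps else 0
    vnew <- v + dt * (0.04 * v^2 + 5 * v + 140 - u - I + eps)
    u <- u + dt * izh$a * (izh$b * v - u)
    if (any(!is.finite(vnew))) stop("integration diverged at step ", step)
    fired <- vnew >= izh$vThresh
    v <- ifelse(fired, izh$c, vnew)
    u <- u + ifelse(fired, izh$d, 0)
    if (any(fired) && bin >= transientBins)
      spikes[fired, bin - transientBins + 1L] <- TRUE
    pl[fired] <- pulseSteps
    rl <- ifelse(pl > 0L, rinf + (rl - rinf) * epul, rl * edec)
    re <- ifelse(pe > 0L, rinf + (re - rinf) * epul, re * edec)
    # flush-to-zero, mirroring the optimized integrator
    rl[rl < 1e-30] <- 0
    re[re < 1e-30] <- 0
    pl <- pmax(pl - 1L, 0L)
    pe <- pmax(pe - 1L, 0L)
  }
  list(spikes = spikes,
       rates = rowSums(spikes) * 1000 / sim$durationMs)
}

#' Run repeated independent trials on one stimulus
#'
#' Derives an independent seed pair per trial from \code{baseSeed} (one for
#' the R-side stimulus noise and Poisson draw, one for the integrator), so
#' every trial sees a fresh noise field and a fresh spike encoding and any
#' trial is reproducible in isolation via its own seeds.
#'
#' @param stimulus a clean \code{\link{StimulusImage}}
#' @param conn a \code{\link{LateralConnectivity}}
#' @param nTrials number of trials
#' @param baseSeed base seed for the trial seed stream
#' @param snr background noise amplitude ratio
#' @param rateHz Poisson rate for fully driven neurons (Hz)
#' @param izh,syn,sim parameter lists
#' @return list of \code{\link{SpikeRecord}} objects
#' @export
runExperiment <- function(stimulus, conn, nTrials = 100, baseSeed = 1,
                          snr = 0.4, rateHz = 40,
                          izh = izhikevichParams(), syn = synapseParams(),
                          sim = simParams()) {
  stopifnot(nTrials >= 1)
  seeds <- trialSeeds(baseSeed, nTrials)
  lapply(seq_len(nTrials), function(t) {
    rec <- tryCatch(
      simulateStimulusTrial(stimulus, conn, seedR = seeds$r[t],
                            seedCpp = seeds$cpp[t], snr = snr,
                            rateHz = rateHz, izh = izh, syn = syn, sim = sim),
      error = function(e) stop("trial ", t, " failed: ", conditionMessage(e)))
    rec
  })
}

#' @rdname runExperiment
#' @param seed base seed
#' @param n number of trials
#' @return \code{trialSeeds}: list of two integer vectors \code{r} (stimulus
#'   noise and Poisson encoding) and \code{cpp} (integrator noise)
#' @export
trialSeeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
        globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 2L * n)
  list(r = s[seq_len(n)], cpp = s[n + seq_len(n)])
}

#' Simulate a single trial from a clean stimulus
#'
#' Convenience wrapper: decomposes the stimulus into orientation channels
#' and encodes the Poisson input with per-bin background noise (see
#' \code{\link{encodePoisson}}), then integrates the network.
#'
#' @inheritParams runExperiment
#' @param seedR seed for the noise and Poisson encoding
#' @param seedCpp seed for the integrator RNG
#' @return a \code{\link{SpikeRecord}}
#' @export
simulateStimulusTrial <- function(stimulus, conn, seedR = 1, seedCpp = 2,
                                  snr = 0.4, rateHz = 40,
                                  izh = izhikevichParams(),
                                  syn = synapseParams(), sim = simParams()) {
  set.seed(seedR)
  channels <- decomposeOrientations(stimulus)
  ext <- encodePoisson(channels, rateHz = rateHz, binMs = sim$binMs,
                       durationMs = sim$transientMs + sim$durationMs,
                       snr = snr)
  runTrial(ext, conn, izh = izh, syn = syn, sim = sim, seed = seedCpp)
}
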