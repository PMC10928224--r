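#' Activation traces from spike trains
#'
#' Causal convolution of binary spike trains with a decaying exponential
#' kernel \eqn{k(t) = e^{-t/\tau_k}} sampled on the analysis grid, computed
#' as the exact recursive filter \eqn{A_t = s_t + \lambda A_{t-1}} with
#' \eqn{\lambda = e^{-binMs/\tau_k}}. The default timescale is 3 ms, of the
#' order of an EPSP; downstream synchrony orderings are insensitive to the
#' choice within 1--10 ms.
#'
#' @param spikes logical/numeric vector or matrix (neurons x bins)
#' @param timescaleMs kernel timescale \eqn{\tau_k} in ms
#' @param binMs bin width of the spike grid in ms
#' @return numeric vector or matrix of nonnegative traces
#' @export
activationTrace <- function(spikes, timescaleMs = 3, binMs = 0.5) {
  stopifnot(timescaleMs > 0)
  lambda <- exp(-binMs / timescaleMs)
  filt <- function(x) as.numeric(stats::filter(as.numeric(x), lambda,
                                               method = "recursive"))
  if (is.matrix(spikes)) t(apply(spikes, 1, filt)) else filt(spikes)
}

#' Zero-lag synchrony (Rsync) of a set of traces
#'
#' \deqn{R_{sync}(S, T) =
#'   \frac{\widehat{Var}_t[\langle A_i(t)\rangle_{i \in S}]}
#'        {\langle \widehat{Var}_t[A_i(t)] \rangle_{i \in S}}}
#' the temporal variance (unbiased, n-1 denominator) of the population-mean
#' activation trace divided by the mean per-neuron temporal variance.
#' Ranges from 0 (out-of-phase firing: constant mean trace) to 1 (identical
#' traces); uncorrelated traces give about 1/N. All-constant traces have a
#' zero denominator and raise an undefined-synchrony error, which is
#' distinct from a true 0.
#'
#' @param traces numeric matrix, neurons x bins (>= 2 rows)
#' @param window optional integer range of bins to restrict the estimate to
#' @return scalar in [0, 1]
#' @export
rsync <- function(traces, window = NULL) {
  stopifnot(is.matrix(traces), nrow(traces) >= 2)
  if (!is.null(window)) traces <- traces[, window, drop = FALSE]
  vars <- apply(traces, 1, stats::var)
  den <- mean(vars)
  if (den == 0)
    stop("undefined synchrony: all traces are constant over the window")
  stats::var(colMeans(traces)) / den
}

#' Randomly select driven neurons from a stimulus segment
#'
#' Uniform sample without replacement from the neurons of the segment that
#' receive external input (see \code{\link{drivenNeurons}}).
#'
#' @param stimulus a clean \code{\link{StimulusImage}}
#' @param segmentId segment label to sample from
#' @param k number of neurons
#' @param seed optional RNG seed for the draw
#' @param driven optional precomputed \code{\link{drivenNeurons}} table
#' @return integer vector of k neuron indices
#' @export
selectNeurons <- function(stimulus, segmentId, k, seed = NULL,
                          driven = NULL) {
  if (is.null(driven)) driven <- drivenNeurons(stimulus)
  pool <- driven$neuron[driven$segment == segmentId]
  if (length(pool) < k)
    stop(sprintf("segment %s has only %d driven neurons, %d requested",
                 segmentId, length(pool), k))
  if (!is.null(seed)) set.seed(seed)
  sample(pool, k)
}

#' Group Rsync over pooled segment selections
#'
#' Selects \code{kPerSegment} driven neurons from every listed segment and
#' measures one Rsync over the pooled group (listing a segment twice doubles
#' its share of the pool).
#'
#' @param record a \code{\link{SpikeRecord}}
#' @param stimulus the clean \code{\link{StimulusImage}} the record was
#'   simulated from
#' @param segmentIds segments to pool
#' @param kPerSegment neurons sampled per listed segment
#' @param seed optional RNG seed for the selection
#' @param timescaleMs activation-kernel timescale (ms)
#' @param window optional bin range
#' @param driven optional precomputed \code{\link{drivenNeurons}} table
#' @return list with elements \code{value}, \code{neurons}, \code{mode}
#' @export
groupRsync <- function(record, stimulus, segmentIds, kPerSegment = 5,
                       seed = NULL, timescaleMs = 3, window = NULL,
                       driven = NULL) {
  if (is.null(driven)) driven <- drivenNeurons(stimulus)
  if (!is.null(seed)) set.seed(seed)
  ids <- unlist(lapply(segmentIds, function(s)
    selectNeurons(stimulus, s, kPerSegment, seed = NULL, driven = driven)))
  traces <- activationTrace(record@spikes[ids, , drop = FALSE],
                            timescaleMs = timescaleMs, binMs = record@binMs)
  list(value = rsync(traces, window = window), neurons = ids, mode = "group")
}

# pairwise Rsync for all row pairs of a trace matrix, from the trace
# covariance: Rsync(i,j) = (v_i + v_j + 2 c_ij) / (2 (v_i + v_j))
pairwiseRsyncMatrix <- function(traces) {
  cm <- stats::cov(t(traces))
  v <- diag(cm)
  vs <- outer(v, v, "+")
  out <- (vs + 2 * cm) / (2 * vs)
  out[vs == 0] <- NA_real_  # degenerate pairs: both traces constant
  diag(out) <- NA_real_
  out
}

#' Average pairwise Rsync between (or within) segments
#'
#' For every driven neuron of \code{segmentA}, the mean of its two-neuron
#' Rsync with every driven neuron of \code{segmentB} (self-pairs excluded
#' when the segments coincide), and symmetrically for neurons of
#' \code{segmentB}. Degenerate pairs (both traces constant) are skipped and
#' counted.
#'
#' @inheritParams groupRsync
#' @param segmentA,segmentB segment labels; equal labels give the
#'   within-segment mode
#' @return list with \code{perNeuron} (data.frame neuron, segment, value),
#'   \code{pairs} (data.frame i, j, value over all cross pairs) and
#'   \code{nDegenerate}
#' @export
avgPairwiseRsync <- function(record, stimulus, segmentA, segmentB,
                             timescaleMs = 3, window = NULL, driven = NULL) {
  if (is.null(driven)) driven <- drivenNeurons(stimulus)
  a <- driven$neuron[driven$segment == segmentA]
  b <- driven$neuron[driven$segment == segmentB]
  stopifnot(length(a) > 0, length(b) > 0)
  ids <- union(a, b)
  traces <- activationTrace(record@spikes[ids, , drop = FALSE],
                            timescaleMs = timescaleMs, binMs = record@binMs)
  if (!is.null(window)) traces <- traces[, window, drop = FALSE]
  pm <- pairwiseRsyncMatrix(traces)
  rownames(pm) <- colnames(pm) <- as.character(ids)
  ia <- match(a, ids); ib <- match(b, ids)
  sub <- pm[ia, ib, drop = FALSE]
  perA <- rowMeans(sub, na.rm = TRUE)
  perB <- colMeans(sub, na.rm = TRUE)
  perNeuron <- rbind(
    data.frame(neuron = a, segment = segmentA, value = perA),
    data.frame(neuron = b, segment = segmentB, value = perB))
  idx <- which(upper.tri(pm, diag = FALSE) &
               (row(pm) %in% ia & col(pm) %in% ib |
                row(pm) %in% ib & col(pm) %in% ia), arr.ind = TRUE)
  pairs <- data.frame(i = ids[idx[, 1]], j = ids[idx[, 2]],
                      value = pm[idx])
  pairs <- pairs[!is.na(pairs$value), , drop = FALSE]
  list(perNeuron = perNeuron, pairs = pairs,
       nDegenerate = sum(is.na(sub)) - sum(a %in% b))
}

#' Spike-time jitter surrogate
#'
#' Re-places every spike of every train uniformly at random within the
#' analysis window, preserving per-train spike counts while destroying
#' temporal alignment. Used as the null control: synchrony differences that
#' survive jittering are rate artefacts, not temporal structure.
#'
#' @param record a \code{\link{SpikeRecord}}
#' @param seed optional RNG seed
#' @return a jittered \code{\link{SpikeRecord}}
#' @export
jitterNull <- function(record, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sp <- record@spikes
  nb <- ncol(sp)
  counts <- rowSums(sp)
  out <- matrix(FALSE, nrow(sp), nb)
  for (i in which(counts > 0))
    out[i, sample.int(nb, counts[i])] <- TRUE
  new("SpikeRecord", spikes = out, binMs = record@binMs, t0Ms = record@t0Ms,
      durationMs = record@durationMs, gridDim = record@gridDim,
      nChannels = record@nChannels, rates = record@rates,
      runaway = record@runaway, seed = record@seed)
}
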