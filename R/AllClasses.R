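#' @import methods
NULL

#' Gestalt stimulus image
#'
#' A small grayscale luminance grid together with integer segment labels that
#' act as ground truth for selecting neurons downstream. Labels partition the
#' lit pixels: 0 marks background (and, for crossing lines, the shared
#' intersection pixel), 1..K mark the stimulus segments.
#'
#' @slot pixels numeric matrix, luminance in [0, 1] (may exceed 1 slightly
#'   after background noise is added).
#' @slot segmentLabels integer matrix of the same dimension; nonzero only at
#'   lit pixels of the clean stimulus.
#' @slot principle one of \code{"proximity"}, \code{"similarity"},
#'   \code{"continuity"}.
#' @slot level the Gestalt parameter: inter-segment gap in pixels
#'   (proximity) or inter-segment/inter-line angle difference in degrees.
#' @export
setClass("StimulusImage",
  representation(pixels = "matrix", segmentLabels = "matrix",
                 principle = "character", level = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!all(dim(object@pixels) == dim(object@segmentLabels)))
      msg <- c(msg, "pixels and segmentLabels must have equal dimensions")
    if (any(object@pixels < 0))
      msg <- c(msg, "luminance values must be nonnegative")
    if (any(object@segmentLabels < 0))
      msg <- c(msg, "segment labels must be nonnegative integers")
    if (!object@principle %in% c("proximity", "similarity", "continuity"))
      msg <- c(msg, "unknown principle")
    if (length(msg)) msg else TRUE
  })

#' Orientation channel stack
#'
#' Output of the oriented edge-detector bank: one nonnegative response grid
#' per preferred orientation. A unit-luminance line at orientation theta
#' yields responses close to 1 along its interior in the channel nearest
#' theta.
#'
#' @slot channels numeric array (height x width x channels), nonnegative.
#' @slot orientations numeric vector of preferred orientations in degrees.
#' @export
setClass("OrientationChannels",
  representation(channels = "array", orientations = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@channels)) != 3L)
      msg <- c(msg, "channels must be a 3-d array")
    else if (dim(object@channels)[3] != length(object@orientations))
      msg <- c(msg, "third dimension must match the number of orientations")
    if (any(object@channels < 0))
      msg <- c(msg, "channel responses must be nonnegative")
    if (length(msg)) msg else TRUE
  })

#' External Poisson spike input
#'
#' Bernoulli event trains on the 0.5 ms analysis grid, one row per neuron in
#' the (channel, pixel) ordering used by the network (see
#' \code{\link{neuronIndex}}).
#'
#' @slot spikes logical matrix, neurons x time bins.
#' @slot rateHz nominal Poisson rate of a fully driven neuron (Hz).
#' @slot binMs bin width in ms.
#' @slot seed RNG seed used for the draw.
#' @export
setClass("ExternalSpikeInput",
  representation(spikes = "matrix", rateHz = "numeric", binMs = "numeric",
                 seed = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!is.logical(object@spikes))
      msg <- c(msg, "spikes must be a logical matrix")
    if (object@binMs <= 0) msg <- c(msg, "binMs must be positive")
    if (object@rateHz < 0) msg <- c(msg, "rateHz must be nonnegative")
    if (length(msg)) msg else TRUE
  })

#' Lateral connectivity of the network
#'
#' The fixed, fully excitatory, symmetric lateral weight structure
#' \deqn{W^{lat}_{ij} = (W^d(i,j) S^d + W^a(i,j) S^a) S^{lat}, \quad i \ne j,}
#' with \eqn{W^d = 1/(L_\infty + 1)} over pixel coordinates (Chebyshev
#' distance) and \eqn{W^a = 1/(\Delta_{\alpha\beta} + 1)} over preferred
#' orientations. Because \eqn{W^d} depends only on the pixel pair and
#' \eqn{W^a} only on the channel pair, the object stores the two small
#' factor matrices; \code{\link[=as.matrix,LateralConnectivity-method]{as.matrix}}
#' materializes the full zero-diagonal N x N matrix.
#'
#' @slot gridDim integer(2): rows, columns of the pixel grid.
#' @slot orientations preferred orientations (degrees) of the channels.
#' @slot distanceWeights P x P matrix of pairwise distance weights.
#' @slot angleWeights K x K matrix of pairwise orientation weights.
#' @slot Sd,Sa,Slat scale factors (spatial, angular, global).
#' @export
setClass("LateralConnectivity",
  representation(gridDim = "integer", orientations = "numeric",
                 distanceWeights = "matrix", angleWeights = "matrix",
                 Sd = "numeric", Sa = "numeric", Slat = "numeric"),
  validity = function(object) {
    msg <- character()
    P <- prod(object@gridDim)
    K <- length(object@orientations)
    if (!all(dim(object@distanceWeights) == c(P, P)))
      msg <- c(msg, "distanceWeights must be P x P")
    if (!all(dim(object@angleWeights) == c(K, K)))
      msg <- c(msg, "angleWeights must be K x K")
    if (any(object@distanceWeights < 0) || any(object@angleWeights < 0))
      msg <- c(msg, "weights must be nonnegative (fully excitatory)")
    if (!isTRUE(all.equal(object@distanceWeights, t(object@distanceWeights))))
      msg <- c(msg, "distanceWeights must be symmetric")
    if (!isTRUE(all.equal(object@angleWeights, t(object@angleWeights))))
      msg <- c(msg, "angleWeights must be symmetric")
    if (object@Sd <= 0 || object@Sa <= 0 || object@Slat < 0)
      msg <- c(msg, "scale factors Sd, Sa must be positive and Slat >= 0")
    if (length(msg)) msg else TRUE
  })

#' Recorded spike trains of one simulation trial
#'
#' Binary spike trains on the 0.5 ms analysis grid with the initial
#' transient excluded.
#'
#' @slot spikes logical matrix, neurons x analysis bins.
#' @slot binMs analysis bin width (ms).
#' @slot t0Ms analysis start time (ms since trial onset; the transient).
#' @slot durationMs analysis window length (ms).
#' @slot gridDim integer(2) pixel grid dimension of the network.
#' @slot nChannels number of orientation channels.
#' @slot rates per-neuron firing rate over the analysis window (Hz).
#' @slot runaway logical flag: population activity exceeded the runaway
#'   threshold (near-saturation firing).
#' @slot seed trial seed.
#' @export
setClass("SpikeRecord",
  representation(spikes = "matrix", binMs = "numeric", t0Ms = "numeric",
                 durationMs = "numeric", gridDim = "integer",
                 nChannels = "integer", rates = "numeric",
                 runaway = "logical", seed = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!is.logical(object@spikes))
      msg <- c(msg, "spikes must be a logical matrix")
    if (nrow(object@spikes) != prod(object@gridDim) * object@nChannels)
      msg <- c(msg, "rows must equal height * width * channels")
    if (abs(ncol(object@spikes) * object@binMs - object@durationMs) > 1e-9)
      msg <- c(msg, "columns must cover durationMs at binMs resolution")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "StimulusImage", function(object) {
  cat(sprintf("StimulusImage: %s stimulus, level %s, %d x %d grid, %d segments, %d lit pixels\n",
              object@principle, format(object@level), nrow(object@pixels),
              ncol(object@pixels), max(object@segmentLabels),
              sum(object@pixels > 0)))
  invisible(object)
})

setMethod("show", "OrientationChannels", function(object) {
  d <- dim(object@channels)
  cat(sprintf("OrientationChannels: %d channels (%s deg) over a %d x %d grid\n",
              d[3], paste(object@orientations, collapse = ", "), d[1], d[2]))
  invisible(object)
})

setMethod("show", "LateralConnectivity", function(object) {
  P <- prod(object@gridDim)
  cat(sprintf(
    "LateralConnectivity: %d x %d grid x %d channels (%d neurons)\n  Sd = %g, Sa = %g, Slat = %g\n",
    object@gridDim[1], object@gridDim[2], length(object@orientations),
    P * length(object@orientations), object@Sd, object@Sa, object@Slat))
  invisible(object)
})

setMethod("show", "SpikeRecord", function(object) {
  cat(sprintf(
    "SpikeRecord: %d neurons x %d bins (%g ms at %g ms), mean rate %.2f Hz%s\n",
    nrow(object@spikes), ncol(object@spikes), object@durationMs, object@binMs,
    mean(object@rates), if (object@runaway) " [RUNAWAY]" else ""))
  invisible(object)
})

# ---- accessors ----------------------------------------------------------

#' @describeIn StimulusImage luminance matrix
#' @param object,x a \code{StimulusImage}
#' @export
pixels <- function(object) object@pixels

#' @describeIn StimulusImage segment label matrix
#' @export
segmentLabels <- function(object) object@segmentLabels

#' @describeIn StimulusImage the Gestalt principle of the stimulus
#' @export
principle <- function(object) object@principle

#' @describeIn StimulusImage the Gestalt parameter (gap or angle difference)
#' @export
gestaltLevel <- function(object) object@level

#' Spike trains of a record
#' @param record a \code{\link{SpikeRecord}}
#' @return logical matrix, neurons x analysis bins
#' @export
spikeTrains <- function(record) record@spikes

#' Per-neuron firing rates (Hz) of a record
#' @param record a \code{\link{SpikeRecord}}
#' @export
firingRates <- function(record) record@rates

#' Runaway-excitation flag of a record
#' @param record a \code{\link{SpikeRecord}}
#' @export
isRunaway <- function(record) record@runaway

#' Materialize the full lateral weight matrix
#'
#' Builds the dense N x N matrix \eqn{W^{lat}} (zero diagonal) from the
#' stored factor matrices. Intended for small grids and for cross-checking;
#' the simulator itself uses the factored form.
#'
#' @param x a \code{\link{LateralConnectivity}}
#' @param ... ignored
#' @return numeric N x N symmetric matrix
#' @export
setMethod("as.matrix", "LateralConnectivity", function(x, ...) {
  P <- prod(x@gridDim)
  K <- length(x@orientations)
  JK <- matrix(1, K, K)
  JP <- matrix(1, P, P)
  W <- x@Slat * (x@Sd * kronecker(JK, x@distanceWeights) +
                 x@Sa * kronecker(x@angleWeights, JP))
  diag(W) <- 0
  W
})

#' Lateral weight between individual neuron pairs
#'
#' Vectorized entrywise lookup of \eqn{W^{lat}_{ij}} without materializing
#' the full matrix.
#'
#' @param conn a \code{\link{LateralConnectivity}}
#' @param i,j neuron indices (equal-length vectors)
#' @return numeric vector of weights (0 for i == j)
#' @export
connWeight <- function(conn, i, j) {
  P <- prod(conn@gridDim)
  pi_ <- (i - 1L) %% P + 1L
  pj <- (j - 1L) %% P + 1L
  ci <- (i - 1L) %/% P + 1L
  cj <- (j - 1L) %/% P + 1L
  w <- conn@Slat * (conn@Sd * conn@distanceWeights[cbind(pi_, pj)] +
                    conn@Sa * conn@angleWeights[cbind(ci, cj)])
  w[i == j] <- 0
  w
}
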