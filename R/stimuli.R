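#' Preferred orientations of the channel bank
#'
#' Five undirected orientations spanning 0--90 degrees at 22.5 degree
#' sensitivity. Stimulus levels are labelled with the rounded values
#' 0, 23, 45, 68, 90; \code{levelToAngle} maps a label to the exact angle.
#'
#' @return numeric vector of 5 orientations in degrees
#' @export
channelOrientations <- function() c(0, 22.5, 45, 67.5, 90)

#' @rdname channelOrientations
#' @param level rounded angle label (one of 0, 23, 45, 68, 90)
#' @export
levelToAngle <- function(level) {
  map <- c("0" = 0, "23" = 22.5, "45" = 45, "68" = 67.5, "90" = 90)
  key <- as.character(level)
  if (any(!key %in% names(map)))
    stop("angle level must be one of 0, 23, 45, 68, 90")
  unname(map[key])
}

# Bresenham rasterization of the segment between two integer grid points;
# returns a (npix x 2) matrix of (row, col). Binary pixels, no anti-aliasing:
# the orientation channels are thresholded downstream anyway.
rasterLine <- function(r0, c0, r1, c1) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- sign(r1 - r0); sc <- sign(c1 - c0)
  err <- dc - dr
  r <- r0; c <- c0
  out <- matrix(0L, dc + dr + 1L, 2L)
  n <- 0L
  repeat {
    n <- n + 1L
    out[n, ] <- c(r, c)
    if (r == r1 && c == c1) break
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c <- c + sc }
    if (e2 <  dc) { err <- err + dc; r <- r + sr }
  }
  out[seq_len(n), , drop = FALSE]
}

newStimulus <- function(pix, lab, principle, level) {
  new("StimulusImage", pixels = pix, segmentLabels = lab,
      principle = principle, level = level)
}

# stamp a set of (row, col) pixels into the image with a segment label,
# skipping pixels that already belong to another segment (labels partition)
stampSegment <- function(pix, lab, coords, id) {
  for (k in seq_len(nrow(coords))) {
    r <- coords[k, 1]; c <- coords[k, 2]
    if (r < 1 || c < 1 || r > nrow(pix) || c > ncol(pix))
      stop("segment leaves the grid; reduce the segment length or gap")
    pix[r, c] <- 1
    if (lab[r, c] == 0L) lab[r, c] <- as.integer(id)
  }
  list(pix = pix, lab = lab)
}

#' Generate a proximity stimulus
#'
#' Two collinear horizontal segments on the centre row, separated by exactly
#' \code{gapPx} background columns. The total stimulus extent
#' (\code{spanPx} columns) is fixed across gaps, so the segment lengths
#' shrink as the gap grows: the two segments jointly cover
#' \code{spanPx - gapPx} pixels (split as evenly as possible, the left
#' segment taking the extra pixel when the split is odd).
#'
#' @param gapPx gap between the segments in pixels (0..4 in the experiments)
#' @param gridSize side of the square pixel grid
#' @param spanPx fixed total extent of the stimulus in columns
#' @return a \code{\link{StimulusImage}} with segments labelled 1 (left)
#'   and 2 (right)
#' @export
generateProximityStimulus <- function(gapPx, gridSize = 20, spanPx = 16) {
  if (!is.numeric(gapPx) || gapPx != round(gapPx) || gapPx < 0)
    stop("gapPx must be a nonnegative integer")
  if (spanPx - gapPx < 2)
    stop("gap too large: both segments must keep at least one pixel")
  if (spanPx > gridSize)
    stop("stimulus span exceeds the grid")
  pix <- matrix(0, gridSize, gridSize)
  lab <- matrix(0L, gridSize, gridSize)
  row <- ceiling(gridSize / 2)
  c0 <- floor((gridSize - spanPx) / 2) + 1L
  lenL <- ceiling((spanPx - gapPx) / 2)
  lenR <- spanPx - gapPx - lenL
  left <- cbind(row, c0:(c0 + lenL - 1L))
  right <- cbind(row, (c0 + spanPx - lenR):(c0 + spanPx - 1L))
  s <- stampSegment(pix, lab, left, 1L)
  s <- stampSegment(s$pix, s$lab, right, 2L)
  newStimulus(s$pix, s$lab, "proximity", gapPx)
}

#' Generate a similarity stimulus
#'
#' Two line segments meeting at a single contact point. Segment 1 is
#' horizontal (orientation 0 degrees, drawn leftwards from the contact
#' pixel, which it owns); segment 2 starts at the adjacent pixel and runs at
#' \code{angleDiffDeg}, so the inter-segment orientation difference equals
#' the level. At 0 degrees the two segments form one straight line of two
#' labelled halves.
#'
#' @param angleDiffDeg angle difference label: 0, 23, 45, 68 or 90
#' @param gridSize side of the square pixel grid
#' @param segLen segment length in pixels
#' @return a \code{\link{StimulusImage}} with segments labelled 1 and 2
#' @export
generateSimilarityStimulus <- function(angleDiffDeg, gridSize = 20,
                                       segLen = 6) {
  theta <- levelToAngle(angleDiffDeg)  # errors on values outside the set
  pix <- matrix(0, gridSize, gridSize)
  lab <- matrix(0L, gridSize, gridSize)
  cr <- ceiling(gridSize / 2); cc <- ceiling(gridSize / 2)
  seg1 <- cbind(cr, (cc - segLen + 1L):cc)
  end <- c(cr - round(segLen * sin(theta * pi / 180)),
           cc + round(segLen * cos(theta * pi / 180)))
  seg2 <- rasterLine(cr, cc, end[1], end[2])
  seg2 <- seg2[-1L, , drop = FALSE]  # contact pixel belongs to segment 1
  s <- stampSegment(pix, lab, seg1, 1L)
  s <- stampSegment(s$pix, s$lab, seg2, 2L)
  newStimulus(s$pix, s$lab, "similarity", angleDiffDeg)
}

#' Generate a continuity stimulus
#'
#' Two lines crossing at the grid centre. Line A is horizontal and
#' contributes segments 1 (left) and 3 (right); line B runs at
#' \code{angleDiffDeg} and contributes segments 2 (upper half) and 4 (lower
#' half), so segments 1 & 3 and 2 & 4 are collinear. The intersection pixel
#' is lit but carries label 0 (shared by both lines). Pixels of line B that
#' coincide with already-labelled line-A pixels near the crossing (shallow
#' angles) keep their line-A label, so labels always partition the pixels.
#'
#' @param angleDiffDeg inter-line angle label: 23, 45, 68 or 90 (0 is
#'   invalid: the two lines would merge and opposite segments coincide)
#' @param gridSize side of the square pixel grid
#' @param halfLen half-line length in pixels
#' @return a \code{\link{StimulusImage}} with segments labelled 1..4
#' @export
generateContinuityStimulus <- function(angleDiffDeg, gridSize = 20,
                                       halfLen = 8) {
  if (isTRUE(all.equal(as.numeric(angleDiffDeg), 0)))
    stop("a 0 degree angle difference is invalid for continuity: the lines merge")
  theta <- levelToAngle(angleDiffDeg)
  pix <- matrix(0, gridSize, gridSize)
  lab <- matrix(0L, gridSize, gridSize)
  cr <- ceiling(gridSize / 2); cc <- ceiling(gridSize / 2)
  seg1 <- cbind(cr, (cc - halfLen):(cc - 1L))            # left
  seg3 <- cbind(cr, (cc + 1L):(cc + halfLen))            # right
  dr <- round(halfLen * sin(theta * pi / 180))
  dc <- round(halfLen * cos(theta * pi / 180))
  seg2 <- rasterLine(cr, cc, cr - dr, cc + dc)[-1L, , drop = FALSE]  # upper
  seg4 <- rasterLine(cr, cc, cr + dr, cc - dc)[-1L, , drop = FALSE]  # lower
  s <- stampSegment(pix, lab, seg1, 1L)
  s <- stampSegment(s$pix, s$lab, seg3, 3L)
  s <- stampSegment(s$pix, s$lab, seg2, 2L)
  s <- stampSegment(s$pix, s$lab, seg4, 4L)
  s$pix[cr, cc] <- 1  # intersection pixel: lit, label 0 (shared)
  newStimulus(s$pix, s$lab, "continuity", angleDiffDeg)
}

#' Add uniform background noise to a stimulus
#'
#' Every pixel gains an independent uniform increment on
#' \code{[0, snr * A]} where \code{A} is the signal amplitude
#' (\code{max(pixels)}, 1 for the generated stimuli). The adopted reading
#' of the signal-to-noise ratio is therefore an amplitude ratio: the noise
#' ceiling is \code{snr} times the signal amplitude, and the mean
#' background level is \code{snr/2}. A fresh field is drawn per call.
#'
#' @param stimulus a \code{\link{StimulusImage}}
#' @param snr noise amplitude as a fraction of the signal amplitude
#' @param seed optional RNG seed for a reproducible field
#' @return a new \code{StimulusImage} with the same labels
#' @export
addBackgroundNoise <- function(stimulus, snr = 0.4, seed = NULL) {
  stopifnot(snr >= 0)
  if (snr == 0) return(stimulus)
  if (!is.null(seed)) set.seed(seed)
  p <- stimulus@pixels
  amp <- max(p)
  if (amp == 0) amp <- 1
  noise <- matrix(stats::runif(length(p), 0, snr * amp), nrow(p), ncol(p))
  newStimulus(p + noise, stimulus@segmentLabels, stimulus@principle,
              stimulus@level)
}

# oriented 5x5 line-matching kernels, one per channel orientation; each is
# the Bresenham raster of a length-5 line through the kernel centre,
# normalized so a unit-luminance line at the matching orientation responds
# with ~1 along its interior
orientationKernels <- function(size = 5) {
  stopifnot(size %% 2 == 1)
  h <- (size - 1L) / 2L
  angles <- channelOrientations()
  lapply(angles, function(theta) {
    dr <- round(h * sin(theta * pi / 180))
    dc <- round(h * cos(theta * pi / 180))
    px <- rasterLine(h + 1 - dr, h + 1 + dc, h + 1 + dr, h + 1 - dc)
    k <- matrix(0, size, size)
    k[px] <- 1
    k / sum(k)
  })
}

# 2-d correlation with zero padding, output size = input size
conv2same <- function(img, kern) {
  kh <- nrow(kern); kw <- ncol(kern)
  hh <- (kh - 1L) / 2L; hw <- (kw - 1L) / 2L
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      w <- kern[i, j]
      if (w == 0) next
      dr <- i - 1L - hh; dc <- j - 1L - hw
      rs <- max(1L, 1L - dr):min(H, H - dr)
      cs <- max(1L, 1L - dc):min(W, W - dc)
      out[rs, cs] <- out[rs, cs] + w * img[rs + dr, cs + dc]
    }
  }
  out
}

#' Decompose a stimulus into orientation channels
#'
#' Convolves the luminance grid with five oriented line-matching kernels
#' (one per preferred orientation, 22.5 degree sensitivity) and half-wave
#' rectifies the result. A pixel on a segment of orientation theta responds
#' maximally in the channel nearest theta; a blank image yields empty
#' channels.
#'
#' @param stimulus a \code{\link{StimulusImage}} or a numeric matrix
#' @return an \code{\link{OrientationChannels}} stack
#' @export
decomposeOrientations <- function(stimulus) {
  img <- if (is(stimulus, "StimulusImage")) stimulus@pixels else stimulus
  kerns <- orientationKernels()
  ch <- array(0, c(nrow(img), ncol(img), length(kerns)))
  for (k in seq_along(kerns)) ch[, , k] <- pmax(conv2same(img, kerns[[k]]), 0)
  new("OrientationChannels", channels = ch,
      orientations = channelOrientations())
}

#' Map grid position and channel to the flat neuron index
#'
#' Neurons are ordered channel-major: all pixels of channel 1 first
#' (column-major within the grid, as in R matrices), then channel 2, etc.
#' \code{neuronIndex} and \code{neuronPosition} are inverse bijections.
#'
#' @param row,col pixel coordinates (1-based)
#' @param channel orientation channel index (1-based)
#' @param gridDim integer(2): grid rows, columns
#' @return \code{neuronIndex}: flat index; \code{neuronPosition}: data.frame
#'   with columns row, col, channel
#' @export
neuronIndex <- function(row, col, channel, gridDim) {
  P <- prod(gridDim)
  (channel - 1L) * P + (col - 1L) * gridDim[1] + row
}

#' @rdname neuronIndex
#' @param id flat neuron index (1-based)
#' @export
neuronPosition <- function(id, gridDim) {
  P <- prod(gridDim)
  channel <- (id - 1L) %/% P + 1L
  p <- (id - 1L) %% P
  data.frame(row = p %% gridDim[1] + 1L, col = p %/% gridDim[1] + 1L,
             channel = channel)
}

#' Encode orientation channels as Poisson spike input
#'
#' A neuron fires in a bin when its channel response, plus the background
#' noise leaking through its kernel in that bin, reaches the relative
#' \code{threshold}, and its independent Bernoulli draw at
#' \code{rateHz * binMs/1000} succeeds. The noise is uniform on
#' \code{[0, snr]} per image pixel and is redrawn at every bin
#' (background fluctuates at the simulation timescale), so its kernel
#' response is the mean of \code{kernelTaps} uniform draws. The effect is
#' a soft threshold on the clean response: stimulus pixels (response ~1)
#' fire at the full rate, the halo around the stimulus (response within
#' reach of the noise) at graded rates, and the far background not at all
#' at the default signal-to-noise ratio — raising \code{snr} toward the
#' threshold floods the background with drive, the input-side signature of
#' runaway excitation.
#'
#' @param channels an \code{\link{OrientationChannels}} stack of the
#'   \emph{clean} stimulus (the per-bin noise is added here)
#' @param rateHz Poisson rate of an active neuron (Hz)
#' @param binMs time bin (ms)
#' @param durationMs total encoded duration (ms); must cover transient plus
#'   analysis window of the simulation
#' @param seed optional RNG seed
#' @param threshold relative channel threshold for a neuron to be driven
#' @param snr background noise amplitude as a fraction of the signal
#'   amplitude
#' @param kernelTaps number of kernel pixels the noise is averaged over
#' @return an \code{\link{ExternalSpikeInput}}
#' @export
encodePoisson <- function(channels, rateHz = 40, binMs = 0.5,
                          durationMs = 1500, seed = NULL, threshold = 0.7,
                          snr = 0.4) {
  p <- rateHz * binMs / 1000
  if (p >= 1) stop("rateHz * binMs must stay below one event per bin")
  if (!is.null(seed)) set.seed(seed)
  ch <- as.vector(channels@channels)  # neurons in channel-major order
  d <- dim(channels@channels)
  P <- d[1] * d[2]
  K <- d[3]
  nbins <- round(durationMs / binMs)
  N <- length(ch)
  # Bernoulli gate of the Poisson process, independent per neuron and bin
  gate <- matrix(stats::runif(N * nbins) < p, N, nbins)
  full <- ch >= threshold
  if (snr == 0 || all(full | ch + snr < threshold)) {
    spikes <- gate & full
  } else {
    # shared per-bin noise field: one uniform draw per image pixel and bin,
    # seen by every kernel that covers the pixel, so threshold crossings of
    # neighbouring halo neurons (and of different channels at one pixel)
    # are correlated, as they are when noise is added to the image itself
    noise <- matrix(stats::runif(P * nbins, 0, snr), P, nbins)
    active <- matrix(FALSE, N, nbins)
    act <- full
    for (k in seq_len(K)) {
      rows <- (k - 1L) * P + seq_len(P)
      margin <- threshold - ch[rows]
      halo <- !full[rows] & margin <= snr  # reachable by the noise
      if (!any(halo)) { active[rows, ] <- full[rows]; next }
      Kc <- .kernelOperator(d[1], d[2], k)   # P x P sparse conv operator
      resp <- Kc[halo, , drop = FALSE] %*% noise
      active[rows[halo], ] <- as.matrix(resp >= margin[halo])
      active[rows[!halo], ] <- full[rows[!halo]]
    }
    spikes <- gate & active
  }
  new("ExternalSpikeInput", spikes = spikes, rateHz = rateHz, binMs = binMs,
      seed = if (is.null(seed)) NA_real_ else seed)
}

# P x P linear operator of channel k's convolution on the pixel grid
# (row i = kernel taps of pixel i), cached per grid size
.kernelOpCache <- new.env(parent = emptyenv())
.kernelOperator <- function(H, W, k) {
  key <- paste(H, W, k, sep = "_")
  got <- .kernelOpCache[[key]]
  if (!is.null(got)) return(got)
  kern <- orientationKernels()[[k]]
  P <- H * W
  op <- matrix(0, P, P)
  kh <- (nrow(kern) - 1L) / 2L
  for (i in seq_len(nrow(kern))) {
    for (j in seq_len(ncol(kern))) {
      w <- kern[i, j]
      if (w == 0) next
      dr <- i - 1L - kh; dc <- j - 1L - kh
      for (col in seq_len(W)) {
        cc <- col + dc
        if (cc < 1 || cc > W) next
        rs <- max(1L, 1L - dr):min(H, H - dr)
        op[cbind((col - 1L) * H + rs, (cc - 1L) * H + rs + dr)] <- w
      }
    }
  }
  .kernelOpCache[[key]] <- op
  op
}

#' Driven neurons of a stimulus
#'
#' A neuron is driven when its clean-stimulus channel response reaches
#' \code{threshold} and its channel is the dominant (maximally responding)
#' channel of its segment, i.e. the neurons that receive external input at
#' (close to) the full Poisson rate and carry the segment's orientation.
#'
#' @param stimulus a clean \code{\link{StimulusImage}} (before noise)
#' @param threshold minimal channel response relative to a full line (1)
#' @return data.frame with columns neuron, row, col, channel, segment
#' @export
drivenNeurons <- function(stimulus, threshold = 0.6) {
  ch <- decomposeOrientations(stimulus)@channels
  lab <- stimulus@segmentLabels
  gd <- dim(lab)
  segs <- sort(unique(lab[lab > 0]))
  out <- NULL
  for (s in segs) {
    m <- lab == s
    resp <- apply(ch, 3, function(x) sum(x[m]))
    dom <- which.max(resp)
    sel <- which(m & ch[, , dom] >= threshold, arr.ind = TRUE)
    if (nrow(sel)) {
      out <- rbind(out, data.frame(
        neuron = neuronIndex(sel[, 1], sel[, 2], dom, gd),
        row = sel[, 1], col = sel[, 2], channel = dom, segment = s))
    }
  }
  out
}
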