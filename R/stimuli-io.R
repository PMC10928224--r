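#' Read and write stimuli as plain text
#'
#' The luminance grid is written as a whitespace-separated numeric grid and
#' the segment labels as a sidecar integer grid (\code{<path>.labels}),
#' with a one-line \code{#} header carrying the principle and level.
#' \code{readStimulusText} round-trips losslessly up to numeric formatting.
#'
#' @param stimulus a \code{\link{StimulusImage}}
#' @param path output file path
#' @return \code{readStimulusText}: a \code{StimulusImage};
#'   \code{writeStimulusText}: the path, invisibly
#' @export
writeStimulusText <- function(stimulus, path) {
  hdr <- sprintf("# principle=%s level=%s", stimulus@principle,
                 format(stimulus@level))
  writeLines(c(hdr, apply(format(stimulus@pixels, digits = 15), 1, paste,
                          collapse = " ")), path)
  writeLines(c(hdr, apply(stimulus@segmentLabels, 1, paste, collapse = " ")),
             paste0(path, ".labels"))
  invisible(path)
}

#' @rdname writeStimulusText
#' @export
readStimulusText <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, regexec("principle=(\\S+) level=(\\S+)", hdr))[[1]]
  pix <- as.matrix(utils::read.table(path, comment.char = "#"))
  lab <- as.matrix(utils::read.table(paste0(path, ".labels"),
                                     comment.char = "#"))
  dimnames(pix) <- dimnames(lab) <- NULL
  new("StimulusImage", pixels = pix, segmentLabels = matrix(as.integer(lab),
      nrow(lab)), principle = m[2], level = as.numeric(m[3]))
}

#' Write a stimulus as a grayscale PNG
#'
#' Luminance is clipped to [0, 1]. Requires the \pkg{png} package.
#'
#' @param stimulus a \code{\link{StimulusImage}}
#' @param path output file path
#' @export
writeStimulusPNG <- function(stimulus, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the png package is required to write PNG images")
  png::writePNG(pmin(pmax(stimulus@pixels, 0), 1), path)
  invisible(path)
}

#' Read a stimulus-generation config from YAML
#'
#' The config lists the principle, its level series, grid size, SNR and
#' Poisson rate; missing fields fall back to the pipeline defaults.
#'
#' @param path YAML file path
#' @return a named list with elements principle, levels, gridSize, snr,
#'   rateHz
#' @export
readStimulusConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(gridSize = 20, snr = 0.4, rateHz = 40)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (is.null(cfg$principle) || is.null(cfg$levels))
    stop("config must name a principle and its level series")
  cfg
}

#' Generate the stimulus series of one experiment
#'
#' @param principle "proximity", "similarity" or "continuity"
#' @param levels level series; defaults to the experiment's full series
#'   (gaps 0..4, angles 0/23/45/68/90, or 23/45/68/90)
#' @param gridSize side of the square grid
#' @return named list of \code{\link{StimulusImage}} objects
#' @export
generateStimulusSeries <- function(principle,
                                   levels = defaultLevels(principle),
                                   gridSize = 20) {
  gen <- switch(principle,
    proximity = generateProximityStimulus,
    similarity = generateSimilarityStimulus,
    continuity = generateContinuityStimulus,
    stop("unknown principle: ", principle))
  stims <- lapply(levels, gen, gridSize = gridSize)
  names(stims) <- as.character(levels)
  stims
}

#' @rdname generateStimulusSeries
#' @export
defaultLevels <- function(principle) {
  switch(principle,
    proximity = 0:4,
    similarity = c(0, 23, 45, 68, 90),
    continuity = c(23, 45, 68, 90),
    stop("unknown principle: ", principle))
}
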