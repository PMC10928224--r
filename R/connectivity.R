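#' Chebyshev (L-infinity) distance between grid points
#'
#' \deqn{L_\infty = \max(|x_2 - x_1|, |y_2 - y_1|)}
#' treats horizontal, vertical and diagonal displacements equally.
#'
#' @param p1,p2 numeric vectors of length 2, or matrices with two columns
#' @return nonnegative distance(s)
#' @export
chebyshevDistance <- function(p1, p2) {
  if (is.null(dim(p1))) p1 <- matrix(p1, ncol = 2)
  if (is.null(dim(p2))) p2 <- matrix(p2, ncol = 2)
  pmax(abs(p2[, 1] - p1[, 1]), abs(p2[, 2] - p1[, 2]))
}

#' Distance weight of a neuron pair
#'
#' \deqn{W^d = 1 / (L_\infty + 1)}: strictly decreasing in distance, 1 for
#' co-located pairs.
#'
#' @param d nonnegative Chebyshev distance(s)
#' @return weight(s) in (0, 1]
#' @export
distanceWeight <- function(d) {
  stopifnot(all(d >= 0))
  1 / (d + 1)
}

#' Undirected circular orientation difference
#'
#' \deqn{\Delta_{\alpha\beta} = 90 - ||\alpha - \beta| - 90|}
#' folds the difference of two undirected orientations into [0, 90].
#'
#' @param alpha,beta orientations in degrees, in [0, 180)
#' @return difference(s) in [0, 90]
#' @export
orientationDifference <- function(alpha, beta) {
  90 - abs(abs(alpha - beta) - 90)
}

#' Orientation weight of a neuron pair
#'
#' \deqn{W^a = 1 / (\Delta_{\alpha\beta} + 1)}
#'
#' @param delta orientation difference(s) in degrees, >= 0
#' @return weight(s) in (0, 1]
#' @export
angleWeight <- function(delta) {
  stopifnot(all(delta >= 0))
  1 / (delta + 1)
}

#' Build the lateral connectivity of the network
#'
#' One neuron per (pixel, orientation channel); a hypercolumn is the K
#' neurons sharing a pixel, and cross-channel pairs at the same pixel have
#' spatial distance 0. The pairwise weight combines spatial proximity and
#' orientation similarity,
#' \deqn{W^{lat}_{ij} = (W^d_{ij} S^d + W^a_{ij} S^a)\, S^{lat},}
#' with zero diagonal (no self-connections) and no inhibitory entries. The
#' default \code{Sd == Sa} gives the two factors equal impact.
#'
#' @param gridDim grid dimension: either a single side length or
#'   \code{c(rows, cols)}
#' @param orientations channel orientations in degrees
#' @param Sd,Sa,Slat scale factors; defaults from
#'   \code{\link{defaultScales}}
#' @return a \code{\link{LateralConnectivity}}
#' @export
buildConnectivity <- function(gridDim = 20,
                              orientations = channelOrientations(),
                              Sd = defaultScales()$Sd,
                              Sa = defaultScales()$Sa,
                              Slat = defaultScales()$Slat) {
  if (length(gridDim) == 1) gridDim <- c(gridDim, gridDim)
  gridDim <- as.integer(gridDim)
  stopifnot(Sd > 0, Sa > 0, Slat >= 0)
  H <- gridDim[1]; W <- gridDim[2]
  coords <- cbind(rep(seq_len(H), times = W), rep(seq_len(W), each = H))
  dmat <- pmax(abs(outer(coords[, 1], coords[, 1], "-")),
               abs(outer(coords[, 2], coords[, 2], "-")))
  Wd <- distanceWeight(dmat)
  Wa <- angleWeight(outer(orientations, orientations, orientationDifference))
  new("LateralConnectivity", gridDim = gridDim, orientations = orientations,
      distanceWeights = Wd, angleWeights = Wa,
      Sd = Sd, Sa = Sa, Slat = Slat)
}

#' Persist and reload a connectivity object
#'
#' Writes a JSON header (grid size, orientations, scale factors) plus the
#' two factor matrices as gzip-compressed text; the loader rebuilds the
#' object and revalidates its invariants (symmetry, nonnegativity,
#' zero diagonal on materialization).
#'
#' @param conn a \code{\link{LateralConnectivity}}
#' @param path base path; \code{<path>.json}, \code{<path>.wd.gz} and
#'   \code{<path>.wa.gz} are written
#' @return \code{loadConnectivity}: the reloaded object
#' @export
saveConnectivity <- function(conn, path) {
  meta <- list(gridDim = conn@gridDim, orientations = conn@orientations,
               Sd = conn@Sd, Sa = conn@Sa, Slat = conn@Slat)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = FALSE,
                       digits = NA)
  for (part in c("wd", "wa")) {
    m <- if (part == "wd") conn@distanceWeights else conn@angleWeights
    con <- gzfile(paste0(path, ".", part, ".gz"), "w")
    utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
    close(con)
  }
  invisible(path)
}

#' @rdname saveConnectivity
#' @export
loadConnectivity <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  rd <- function(part) {
    m <- as.matrix(utils::read.table(gzfile(paste0(path, ".", part, ".gz"))))
    dimnames(m) <- NULL
    m
  }
  conn <- new("LateralConnectivity", gridDim = as.integer(meta$gridDim),
              orientations = meta$orientations, distanceWeights = rd("wd"),
              angleWeights = rd("wa"), Sd = meta$Sd, Sa = meta$Sa,
              Slat = meta$Slat)
  validObject(conn)  # invariants re-checked on read
  conn
}
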