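## Segments -> continuous pseudo-activation maps via the Gaussian
## radial-basis affinity transform.

#' Peak activation points of a segmentation
#'
#' For 1-D segmentations the two terminal segments take their peak on the
#' boundary farther from the contiguous segment, i.e. at the extreme data
#' value on the far side. Interior segments use the method-specific anchor:
#' the median for PCT, the centroid ("center of inertia") for KMeans, and the
#' local density maximum for KDE. For multidimensional clusterings (no
#' boundaries) every cluster's peak is its centroid.
#'
#' @param segmentation a \linkS4class{Segmentation}.
#' @return k-by-d matrix of peak coordinates in gradient space (d = 1 for
#'   axis segmentations).
#' @export
computePeaks <- function(segmentation) {
  stopifnot(is(segmentation, "Segmentation"))
  X <- segmentPoints(segmentation)
  labels <- segmentLabels(segmentation)
  k <- nSegments(segmentation)
  if (any(tabulate(labels, k) == 0)) stopUser("empty segment in segmentation")
  if (ncol(X) > 1 || length(segmentBoundaries(segmentation)) == 0)
    return(segmentAnchors(segmentation))
  v <- X[, 1]
  peaks <- segmentAnchors(segmentation)[, 1]
  peaks[1] <- min(v[labels == 1])        # terminal: far boundary = extreme
  peaks[k] <- max(v[labels == k])
  matrix(peaks, ncol = 1)
}

#' Gaussian RBF pseudo-activation map for one segment
#'
#' Affinity of every segment member to the peak point,
#' \code{A = exp(-D^2 / (2 sigma^2))} with D the Euclidean distance in
#' gradient space; vertices outside the segment are set to 0 so all maps share
#' a fixed full-cortex support. By default sigma is the mean distance of
#' segment members to the peak; \code{sigmaMethod = "pairwise"} uses the mean
#' pairwise distance within the segment instead.
#'
#' @param points n-by-d gradient coordinates (or 1-D vector).
#' @param labels integer segment labels.
#' @param peak peak coordinates (length d).
#' @param segmentId which segment this map describes.
#' @param sigmaMethod \code{"to_peak"} (default) or \code{"pairwise"}.
#' @return A \linkS4class{PseudoActivationMap}.
#' @export
rbfMap <- function(points, labels, peak, segmentId,
                   sigmaMethod = c("to_peak", "pairwise")) {
  sigmaMethod <- match.arg(sigmaMethod)
  X <- asPointMatrix(points)
  labels <- as.integer(labels)
  segmentId <- as.integer(segmentId)
  members <- labels == segmentId
  if (!any(members)) stopUser("segment %d is empty", segmentId)
  D <- distToPoint(X, as.numeric(peak))
  sigma <- if (sigmaMethod == "to_peak") {
    mean(D[members])
  } else {
    Xm <- X[members, , drop = FALSE]
    dm <- crossDist(Xm, Xm)
    mean(dm[upper.tri(dm)])
  }
  if (!is.finite(sigma) || sigma <= 0)
    stopUser("degenerate segment %d: sigma is zero (needs >= 2 distinct points)",
             segmentId)
  vals <- numeric(nrow(X))
  vals[members] <- exp(-D[members]^2 / (2 * sigma^2))
  new("PseudoActivationMap", segmentId = segmentId, values = vals,
      sigma = sigma, peak = as.numeric(peak))
}

#' Pseudo-activation map set for a whole segmentation
#'
#' One RBF map per segment, each a full-cortex vector that is zero outside its
#' segment; together the maps' supports partition the vertices.
#'
#' @param segmentation a \linkS4class{Segmentation}.
#' @param peaks optional k-by-d peak matrix; computed with
#'   \code{\link{computePeaks}} when missing.
#' @param sigmaMethod passed to \code{\link{rbfMap}}.
#' @return List of \linkS4class{PseudoActivationMap}, one per segment.
#' @export
buildMapSet <- function(segmentation, peaks = NULL,
                        sigmaMethod = c("to_peak", "pairwise")) {
  sigmaMethod <- match.arg(sigmaMethod)
  if (is.null(peaks)) peaks <- computePeaks(segmentation)
  X <- segmentPoints(segmentation)
  labels <- segmentLabels(segmentation)
  lapply(seq_len(nSegments(segmentation)), function(j) {
    rbfMap(X, labels, peaks[j, ], j, sigmaMethod = sigmaMethod)
  })
}

# Stack a list of pseudo-activation maps into an n-by-k matrix.
mapSetMatrix <- function(maps) {
  vapply(maps, mapValues, numeric(length(mapValues(maps[[1]]))))
}
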