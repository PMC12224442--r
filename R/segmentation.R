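## Segmentation of the gradient axis (1-D) or joint gradient space (n-D),
## plus clustering-quality metrics.

newSegmentation <- function(method, k, labels, boundaries, points, anchors,
                            extras = list()) {
  new("Segmentation", method = method, k = as.integer(k),
      labels = as.integer(labels), boundaries = as.numeric(boundaries),
      points = asPointMatrix(points), anchors = asPointMatrix(anchors),
      extras = extras)
}

checkSegInput <- function(values, k) {
  if (!is.numeric(k) || length(k) != 1 || k < 2)
    stopUser("k must be an integer >= 2")
  if (length(unique(round(values, 12))) < k)
    stopUser("degenerate segmentation: fewer than k distinct values")
}

#' Percentile segmentation of the gradient axis
#'
#' Splits the axis at the j*(100/k)-th percentiles (linear interpolation),
#' giving segments of equal population up to one vertex.
#'
#' @param values per-vertex gradient coordinates (1-D).
#' @param k number of segments, >= 2.
#' @return A \linkS4class{Segmentation} with method \code{"PCT"}; anchors are
#'   segment medians.
#' @export
segmentPct <- function(values, k) {
  values <- as.numeric(values)
  checkSegInput(values, k)
  n <- length(values)
  boundaries <- stats::quantile(values, probs = seq_len(k - 1) / k,
                                names = FALSE, type = 7)
  # assign by rank so populations stay balanced even with ties at a boundary
  sizes <- diff(floor(seq(0, n, length.out = k + 1)))
  labels <- integer(n)
  labels[order(values, seq_len(n))] <- rep.int(seq_len(k), sizes)
  if (is.unsorted(boundaries, strictly = TRUE))
    stopUser("degenerate segmentation: duplicated percentile boundaries")
  anchors <- vapply(seq_len(k), function(j) stats::median(values[labels == j]),
                    numeric(1))
  newSegmentation("PCT", k, labels, boundaries, values, anchors)
}

# k-means++ seeding followed by Lloyd iterations; nstart restarts, best SSE.
kmeansEngine <- function(X, k, seed, nstart = 10, iterMax = 300) {
  X <- asPointMatrix(X)
  if (nrow(unique(X)) < k)
    stopUser("degenerate clustering: fewer than k distinct points")
  withSeed(seed, {
    best <- NULL
    for (s in seq_len(nstart)) {
      centers <- kmeansPlusPlusSeed(X, k)
      fit <- suppressWarnings(
        stats::kmeans(X, centers = centers, iter.max = iterMax))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    best
  })
}

kmeansPlusPlusSeed <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums((X - X[rep(idx[1], n), , drop = FALSE])^2)
  for (j in 2:k) {
    prob <- d2 / sum(d2)
    idx[j] <- sample.int(n, 1, prob = prob)
    d2 <- pmin(d2, rowSums((X - X[rep(idx[j], n), , drop = FALSE])^2))
  }
  X[idx, , drop = FALSE]
}

relabelByCentroid <- function(fit) {
  ord <- order(fit$centers[, 1])
  relab <- integer(length(ord)); relab[ord] <- seq_along(ord)
  list(labels = relab[fit$cluster],
       centers = fit$centers[ord, , drop = FALSE])
}

#' 1-D k-means segmentation of the gradient axis
#'
#' k-means++ seeded clustering with restarts; clusters are relabeled in
#' increasing centroid order so labels are monotone along the axis, and the
#' centroids ("centers of inertia") are kept as anchors. Boundaries are the
#' midpoints between consecutive centroids.
#'
#' @param values per-vertex gradient coordinates (1-D).
#' @param k number of segments, >= 2.
#' @param seed RNG seed for the restarts.
#' @param nstart number of k-means++ restarts.
#' @return A \linkS4class{Segmentation} with method \code{"KMeans"}.
#' @export
segmentKmeans <- function(values, k, seed = NULL, nstart = 10) {
  values <- as.numeric(values)
  checkSegInput(values, k)
  fit <- kmeansEngine(matrix(values, ncol = 1), k, seed, nstart = nstart)
  rl <- relabelByCentroid(fit)
  centers <- rl$centers[, 1]
  boundaries <- (centers[-k] + centers[-1]) / 2
  newSegmentation("KMeans", k, rl$labels, boundaries, values, centers,
                  extras = list(totWithinss = fit$tot.withinss))
}

#' k-means clustering in joint gradient space
#'
#' The n-dimensional analogue of \code{\link{segmentKmeans}}: clusters
#' vertices in the joint space of several gradients. Labels are ordered by the
#' first-gradient coordinate of the centroids; anchors are the centroids.
#'
#' @param gradients n-by-d matrix of gradient coordinates (1 <= d <= 9).
#' @param k number of clusters.
#' @param seed RNG seed.
#' @param nstart number of restarts.
#' @return A \linkS4class{Segmentation} (no boundaries in n-D).
#' @export
multidimCluster <- function(gradients, k, seed = NULL, nstart = 10) {
  X <- asPointMatrix(gradients)
  if (ncol(X) < 1 || ncol(X) > 9)
    stopUser("gradient space must have between 1 and 9 dimensions")
  if (!is.numeric(k) || k < 2) stopUser("k must be >= 2")
  fit <- kmeansEngine(X, k, seed)
  rl <- relabelByCentroid(fit)
  boundaries <- if (ncol(X) == 1)
    (rl$centers[-k, 1] + rl$centers[-1, 1]) / 2 else numeric(0)
  newSegmentation("KMeans", k, rl$labels, boundaries, X, rl$centers,
                  extras = list(totWithinss = fit$tot.withinss))
}

# Locate interior local minima/maxima of a discretized curve. Equal-value
# plateaus are compressed; a plateau extremum reports its midpoint.
curveExtrema <- function(xGrid, y) {
  r <- rle(y)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nR <- length(r$values)
  minima <- numeric(0); maxima <- numeric(0)
  if (nR >= 3) {
    for (i in 2:(nR - 1)) {
      mid <- (xGrid[starts[i]] + xGrid[ends[i]]) / 2
      if (r$values[i] < r$values[i - 1] && r$values[i] < r$values[i + 1])
        minima <- c(minima, mid)
      if (r$values[i] > r$values[i - 1] && r$values[i] > r$values[i + 1])
        maxima <- c(maxima, mid)
    }
  }
  list(minima = minima, maxima = maxima)
}

kdeCurve <- function(values, bw, gridSize) {
  stats::density(values, bw = bw, kernel = "gaussian", n = gridSize,
                 from = min(values) - 3 * bw, to = max(values) + 3 * bw)
}

#' KDE-based segmentation of the gradient axis
#'
#' Evaluates a Gaussian kernel density estimate of the gradient values on a
#' uniform grid and places boundaries at the interior local minima of the
#' curve -- points with the fewest vertices in their vicinity. The bandwidth is
#' tuned by bisection on the log scale until the curve has exactly k-1
#' interior minima; anchors are the local density maxima between consecutive
#' minima.
#'
#' @param values per-vertex gradient coordinates (1-D).
#' @param k number of segments, >= 2.
#' @param gridSize number of uniform grid points for the density curve.
#' @param bandwidthRange bandwidth search range as a fraction of the data
#'   range.
#' @param maxIter bisection iterations.
#' @return A \linkS4class{Segmentation} with method \code{"KDE"}; extras carry
#'   the tuned bandwidth and the density curve.
#' @export
segmentKde <- function(values, k, gridSize = 1024,
                       bandwidthRange = c(1e-3, 1), maxIter = 60) {
  values <- as.numeric(values)
  checkSegInput(values, k)
  target <- k - 1L
  rng <- diff(range(values))
  lo <- log(bandwidthRange[1] * rng)
  hi <- log(bandwidthRange[2] * rng)
  countMinima <- function(logBw) {
    d <- kdeCurve(values, exp(logBw), gridSize)
    length(curveExtrema(d$x, d$y)$minima)
  }
  seen <- integer(0)
  found <- NA_real_
  for (it in seq_len(maxIter)) {
    mid <- (lo + hi) / 2
    cnt <- countMinima(mid)
    seen <- union(seen, cnt)
    if (cnt == target) { found <- mid; break }
    if (cnt > target) lo <- mid else hi <- mid
  }
  if (is.na(found))
    stopUser(paste0("KDE bandwidth tuning failed: no bandwidth in range gives ",
                    "%d boundaries (achievable counts seen: %s)"),
             target, paste(sort(seen), collapse = ", "))
  bw <- exp(found)
  d <- kdeCurve(values, bw, gridSize)
  ext <- curveExtrema(d$x, d$y)
  boundaries <- ext$minima
  labels <- findInterval(values, boundaries) + 1L
  if (!all(seq_len(k) %in% labels))
    stopUser("KDE segmentation produced an empty segment")
  # anchor = density argmax between consecutive boundaries (incl. ends)
  edges <- c(-Inf, boundaries, Inf)
  anchors <- vapply(seq_len(k), function(j) {
    inside <- d$x > edges[j] & d$x < edges[j + 1]
    d$x[inside][which.max(d$y[inside])]
  }, numeric(1))
  newSegmentation("KDE", k, labels, boundaries, values, anchors,
                  extras = list(bandwidth = bw, grid = d$x, density = d$y))
}

#' Per-vertex silhouette confidence map
#'
#' Silhouette coefficient of every vertex with respect to its assigned
#' segment: (b - a) / max(a, b) with a the mean intra-cluster distance and b
#' the smallest mean distance to another cluster. Vertices in singleton
#' clusters score 0.
#'
#' @param points n-by-d coordinates (or a 1-D vector).
#' @param labels integer cluster labels.
#' @return Numeric vector of silhouette coefficients in [-1, 1].
#' @export
silhouetteMap <- function(points, labels) {
  X <- asPointMatrix(points)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stopUser("silhouette undefined for a single cluster")
  if (any(tabulate(labels) == 0)) stopUser("all clusters must be nonempty")
  sil <- cluster::silhouette(labels, stats::dist(X))
  out <- as.numeric(sil[, "sil_width"])
  out
}

#' Clustering quality metrics for a segmentation
#'
#' Mean silhouette coefficient, variance ratio (Calinski-Harabasz) and cluster
#' separation (Davies-Bouldin). Higher silhouette and variance ratio and lower
#' cluster separation indicate better relative performance.
#'
#' @param points n-by-d coordinates.
#' @param labels integer cluster labels.
#' @return Named list with \code{meanSilhouette}, \code{varianceRatio} and
#'   \code{clusterSeparation}.
#' @export
clusterQuality <- function(points, labels) {
  X <- asPointMatrix(points)
  labels <- as.integer(labels)
  ms <- mean(silhouetteMap(X, labels))
  ks <- sort(unique(labels))
  k <- length(ks)
  n <- nrow(X)
  grand <- colMeans(X)
  cen <- vapply(ks, function(j) colMeans(X[labels == j, , drop = FALSE]),
                numeric(ncol(X)))
  centers <- if (is.matrix(cen)) t(cen) else matrix(cen, ncol = 1)
  sizes <- vapply(ks, function(j) sum(labels == j), integer(1))
  B <- sum(sizes * rowSums((centers - matrix(grand, k, ncol(X), byrow = TRUE))^2))
  W <- sum(vapply(seq_along(ks), function(i) {
    Xi <- X[labels == ks[i], , drop = FALSE]
    sum((Xi - matrix(centers[i, ], nrow(Xi), ncol(X), byrow = TRUE))^2)
  }, numeric(1)))
  ch <- if (W == 0) Inf else (B / (k - 1)) / (W / (n - k))
  # Davies-Bouldin: mean over clusters of the worst (s_i + s_j) / d_ij
  s <- vapply(seq_along(ks), function(i) {
    Xi <- X[labels == ks[i], , drop = FALSE]
    mean(distToPoint(Xi, centers[i, ]))
  }, numeric(1))
  cd <- crossDist(centers, centers)
  db <- mean(vapply(seq_len(k), function(i) {
    max(vapply(seq_len(k)[-i], function(j) (s[i] + s[j]) / cd[i, j],
               numeric(1)))
  }, numeric(1)))
  list(meanSilhouette = ms, varianceRatio = ch, clusterSeparation = db)
}

#' Normalized mutual information between two labelings
#'
#' Mutual information normalized by the arithmetic mean of the two label
#' entropies; 1 for identical partitions (up to relabeling), near 0 for
#' independent ones.
#'
#' @param labelsA,labelsB integer label vectors of equal length.
#' @return NMI in [0, 1].
#' @export
nmi <- function(labelsA, labelsB) {
  if (length(labelsA) == 0 || length(labelsA) != length(labelsB))
    stopUser("labelings must be nonempty and of equal length")
  tab <- table(labelsA, labelsB)
  n <- sum(tab)
  pij <- tab / n
  pi <- rowSums(pij); pj <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi, pj)[nz]))
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  denom <- (h(pi) + h(pj)) / 2
  if (denom == 0) return(1)        # both labelings constant and identical
  max(0, min(1, mi / denom))
}
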