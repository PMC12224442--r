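## Connectome -> gradients: inverse Fisher transform, row sparsification,
## cosine affinity, diffusion map embedding, explained variance.

#' Inverse Fisher transform of a z-valued connectome
#'
#' Maps Fisher z-scores back to correlation coefficients by the elementwise
#' hyperbolic tangent, bounding the connectome in [-1, 1].
#'
#' @param connectome a z-valued \linkS4class{DenseConnectome}.
#' @return An r-valued \linkS4class{DenseConnectome}.
#' @export
inverseFisher <- function(connectome) {
  stopifnot(is(connectome, "DenseConnectome"))
  if (valueKind(connectome) != "z")
    stopUser("inverseFisher expects a z-valued connectome")
  DenseConnectome(tanh(connectivityValues(connectome)),
                  vertexIds(connectome), valueKind = "r")
}

#' Row-wise sparsification of a connectivity matrix
#'
#' Retains, independently for every row, the top \code{ceiling(density * n)}
#' strongest connections and zeroes the rest. Ties at the cutoff are resolved
#' deterministically by keeping the lowest column index. The output is in
#' general asymmetric.
#'
#' @param x an r-valued \linkS4class{DenseConnectome} or a numeric matrix.
#' @param density fraction of connections to keep per row, in (0, 1].
#' @return A numeric matrix of the same dimension.
#' @export
rowSparsify <- function(x, density = 0.10) {
  if (is(x, "DenseConnectome")) x <- connectivityValues(x)
  if (!is.matrix(x)) stopUser("rowSparsify expects a matrix or DenseConnectome")
  if (!is.numeric(density) || length(density) != 1 || density <= 0 || density > 1)
    stopUser("density must lie in (0, 1]")
  n <- ncol(x)
  m <- as.integer(ceiling(density * n))
  if (m >= n) return(x)
  out <- matrix(0, nrow(x), n, dimnames = dimnames(x))
  for (i in seq_len(nrow(x))) {
    row <- x[i, ]
    keep <- order(-row, seq_len(n))[seq_len(m)]
    out[i, keep] <- row[keep]
  }
  out
}

#' Cosine similarity between connectivity rows
#'
#' Builds the affinity matrix whose (i, j) entry is the cosine of the angle
#' between rows i and j of the (sparsified) connectivity matrix.
#'
#' @param x numeric matrix (rows = vertices' connectivity profiles).
#' @return Symmetric matrix with unit diagonal, values in [-1, 1].
#' @export
cosineAffinity <- function(x) {
  if (!is.matrix(x)) stopUser("cosineAffinity expects a matrix")
  nrm <- sqrt(rowSums(x^2))
  zero <- which(nrm == 0)
  if (length(zero))
    stopUser("degenerate vertex: all-zero connectivity row(s) %s",
             paste(utils::head(zero, 5), collapse = ", "))
  aff <- tcrossprod(x / nrm)
  aff[aff > 1] <- 1
  aff[aff < -1] <- -1
  diag(aff) <- 1
  (aff + t(aff)) / 2
}

#' Diffusion map embedding of an affinity matrix
#'
#' Eigendecomposes the anisotropic-diffusion normalized operator of the
#' affinity graph (alpha-normalization followed by row-stochastic scaling,
#' solved through its symmetric conjugate). The trivial constant eigenvector
#' is discarded; remaining components are scaled by
#' \code{lambda / (1 - lambda)} (multi-scale weighting, diffusion time 0) and
#' sign-fixed so that the vertex with the largest absolute loading is
#' positive. Negative affinities are clipped to zero beforehand so the
#' operator stays normalizable.
#'
#' @param affinity symmetric affinity matrix (e.g. from
#'   \code{\link{cosineAffinity}}).
#' @param nComponents number of non-trivial components to retain.
#' @param alpha anisotropic normalization exponent; 0.5 balances geometry
#'   against sampling density.
#' @param seed unused by the deterministic dense solver; accepted for
#'   interface stability.
#' @return A \linkS4class{GradientSet}.
#' @export
diffusionEmbedding <- function(affinity, nComponents = 9, alpha = 0.5,
                               seed = NULL) {
  if (!is.matrix(affinity) || nrow(affinity) != ncol(affinity))
    stopUser("affinity must be a square matrix")
  n <- nrow(affinity)
  if (nComponents >= n) stopUser("nComponents must be smaller than n vertices")
  L <- affinity
  L[L < 0] <- 0
  d <- rowSums(L)
  if (any(d == 0))
    warning("affinity graph has isolated vertices; embedding may be degenerate")
  d[d == 0] <- .Machine$double.eps
  La <- L / outer(d^alpha, d^alpha)
  d2 <- rowSums(La)
  inv <- 1 / sqrt(d2)
  S <- La * outer(inv, inv)
  S <- (S + t(S)) / 2
  eig <- eigen(S, symmetric = TRUE)
  m <- nComponents + 1L          # room for the trivial eigenvector
  lambda <- eig$values[seq_len(m)]
  psi <- eig$vectors[, seq_len(m), drop = FALSE] * inv
  # detect the trivial (near-constant) eigenvector by coefficient of variation
  cv <- apply(psi, 2, function(v) stats::sd(v) / max(abs(mean(v)), 1e-300))
  trivial <- which(cv < 1e-6)
  trivial <- if (length(trivial)) trivial[1] else 1L
  keep <- setdiff(seq_len(m), trivial)[seq_len(nComponents)]
  lambda <- lambda[keep]
  if (any(lambda < 0)) {
    lambda[lambda < 0] <- 0
  }
  scale <- lambda / pmax(1 - lambda, .Machine$double.eps)
  comp <- psi[, keep, drop = FALSE] *
    matrix(scale, n, length(keep), byrow = TRUE)
  # deterministic sign: largest-|loading| vertex positive
  for (j in seq_len(ncol(comp))) {
    i <- which.max(abs(comp[, j]))
    if (comp[i, j] < 0) comp[, j] <- -comp[, j]
  }
  ev <- explainedVarianceRatios(lambda)
  ord <- order(ev, decreasing = TRUE)
  colnames(comp) <- NULL
  new("GradientSet", components = comp[, ord, drop = FALSE],
      eigenvalues = lambda[ord], explainedVariance = ev[ord])
}

#' Explained-variance ratios from eigenvalues
#'
#' @param eigenvalues nonnegative eigenvalues of retained non-trivial
#'   components.
#' @return Ratios \code{lambda / sum(lambda)}, summing to 1.
#' @export
explainedVarianceRatios <- function(eigenvalues) {
  if (any(eigenvalues < 0)) stopUser("eigenvalues must be >= 0")
  s <- sum(eigenvalues)
  if (s == 0) stopUser("all eigenvalues are zero; variance ratios undefined")
  eigenvalues / s
}

#' Run the full gradient decomposition of a connectome
#'
#' Convenience wrapper chaining the inverse Fisher transform (for z-valued
#' input), row sparsification, cosine affinity and diffusion embedding.
#'
#' @param connectome a \linkS4class{DenseConnectome}.
#' @param density row sparsification density.
#' @param nComponents number of gradients to retain.
#' @param alpha diffusion normalization exponent.
#' @return A \linkS4class{GradientSet}.
#' @export
connectomeGradients <- function(connectome, density = 0.10, nComponents = 9,
                                alpha = 0.5) {
  stopifnot(is(connectome, "DenseConnectome"))
  if (valueKind(connectome) == "z") connectome <- inverseFisher(connectome)
  sparse <- rowSparsify(connectome, density = density)
  diffusionEmbedding(cosineAffinity(sparse), nComponents = nComponents,
                     alpha = alpha)
}
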