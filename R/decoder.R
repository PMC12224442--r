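## Correlation decoding with spin-permutation spatial nulls and BH FDR.

# Coerce a map set (list of MetaAnalyticMap / PseudoActivationMap / numeric
# vectors, or a matrix) to an n-by-m matrix with map labels as column names.
mapMatrix <- function(maps) {
  if (is.matrix(maps)) return(maps)
  if (is.numeric(maps)) return(matrix(maps, ncol = 1))
  cols <- lapply(maps, function(m) {
    if (is(m, "MetaAnalyticMap") || is(m, "PseudoActivationMap")) mapValues(m)
    else as.numeric(m)
  })
  out <- do.call(cbind, cols)
  labs <- names(maps)
  if (is.null(labs)) {
    labs <- vapply(seq_along(maps), function(i) {
      m <- maps[[i]]
      if (is(m, "MetaAnalyticMap")) paste(mapLabels(m), collapse = "_")
      else if (is(m, "PseudoActivationMap")) paste0("segment", m@segmentId)
      else paste0("map", i)
    }, character(1))
  }
  colnames(out) <- labs
  out
}

#' Correlate a target map against a labeled map set
#'
#' Pearson correlation of the (unthresholded) target map with every map in the
#' set, ranked by descending correlation; ties are ordered by label.
#' Zero-variance maps in the set are excluded with a warning.
#'
#' @param target numeric vertex map (nonzero variance).
#' @param mapSet list of labeled maps or an n-by-m matrix with labeled
#'   columns.
#' @return data.frame with columns \code{label} and \code{r}, sorted.
#' @export
correlateMaps <- function(target, mapSet) {
  M <- mapMatrix(mapSet)
  target <- as.numeric(target)
  if (stats::sd(target) == 0) stopUser("target map has zero variance")
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("excluding %d zero-variance map(s) from ranking",
                    sum(sds == 0)))
    M <- M[, sds > 0, drop = FALSE]
  }
  r <- as.numeric(stats::cor(target, M))
  ord <- order(-r, colnames(M))
  data.frame(label = colnames(M)[ord], r = r[ord], stringsAsFactors = FALSE)
}

randomRotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a uniform rotation (det +1)
  qr0 <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr0)
  Q <- Q %*% diag(sign(diag(qr.R(qr0))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Spin permutations of a spherical mesh
#'
#' Generates spatial null permutations by randomly rotating the spherical
#' projection of the cortex and reassigning each vertex to the nearest rotated
#' vertex without replacement (greedy bijection). Left-hemisphere rotations
#' are mirrored across the midline to the right hemisphere; medial-wall
#' vertices are never moved. Each permutation row is a bijection on cortex
#' vertices, so spun maps preserve the value multiset exactly while keeping
#' the spatial autocorrelation structure.
#'
#' @param mesh a \linkS4class{SphereMesh}.
#' @param nPerm number of permutations (default 1000).
#' @param seed RNG seed; identical seeds reproduce identical index arrays.
#' @return Integer matrix nPerm-by-nCortex of indices into the cortex
#'   vertices, with the seed and cortex indices as attributes.
#' @export
spinNulls <- function(mesh, nPerm = 1000, seed = NULL) {
  stopifnot(is(mesh, "SphereMesh"))
  cortex <- which(cortexMask(mesh))
  if (length(cortex) < 3) stopUser("cortex smaller than 3 vertices")
  XYZ <- meshCoordinates(mesh)[cortex, , drop = FALSE]
  hemi <- hemisphere(mesh)[cortex]
  mirror <- diag(c(-1, 1, 1))
  nC <- length(cortex)
  perms <- matrix(0L, nPerm, nC)
  withSeed(seed, {
    for (p in seq_len(nPerm)) {
      R <- randomRotation()
      visit <- sample.int(nC)
      for (h in unique(hemi)) {
        inH <- which(hemi == h)
        Rh <- if (h == "R") mirror %*% R %*% mirror else R
        rot <- XYZ[inH, , drop = FALSE] %*% t(Rh)
        ordH <- order(match(inH, visit))   # hemisphere-local visit order
        perms[p, inH] <- inH[greedyAssign(XYZ[inH, , drop = FALSE], rot, ordH)]
      }
    }
  })
  attr(perms, "seed") <- seed
  attr(perms, "cortex") <- cortex
  perms
}

#' Permutation p-value from a null distribution
#'
#' Fraction of null correlations equal to or greater than the observed one
#' (one-sided). The literal fraction k/n can return exactly 0; the
#' \code{"plus_one"} estimator (k+1)/(n+1) avoids that at the cost of a
#' minimum attainable p of 1/(n+1).
#'
#' @param rObs observed correlation.
#' @param rNull numeric vector of null correlations.
#' @param estimator \code{"fraction"} (default) or \code{"plus_one"}.
#' @return p-value in [0, 1].
#' @export
permPvalue <- function(rObs, rNull, estimator = c("fraction", "plus_one")) {
  estimator <- match.arg(estimator)
  if (length(rNull) == 0) stopUser("null set is empty")
  k <- sum(rNull >= rObs)
  if (estimator == "fraction") k / length(rNull)
  else (k + 1) / (length(rNull) + 1)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up procedure; adjusted values are monotone nondecreasing in
#' the sorted order and capped at 1.
#'
#' @param pvalues vector of p-values in [0, 1].
#' @param alpha significance level for the mask.
#' @return List with \code{q} (adjusted values) and \code{significant}
#'   (logical, \code{q < alpha}).
#' @export
fdrBH <- function(pvalues, alpha = 0.05) {
  if (any(pvalues < 0 | pvalues > 1)) stopUser("p-values must lie in [0, 1]")
  q <- stats::p.adjust(pvalues, method = "BH")
  list(q = q, significant = q < alpha)
}

#' Decode a pseudo-activation map set against meta-analytic maps
#'
#' For every (segment, meta map) pair: Pearson correlation over cortex
#' vertices, a spin-permutation p-value (by default the meta-analytic maps are
#' spun, matching the null of maps with identical spatial autocorrelation),
#' and BH FDR adjustment across all pairs of the run; significance is
#' \code{q < alpha}.
#'
#' @param targetMaps list of \linkS4class{PseudoActivationMap} (or matrix);
#'   full-mesh vectors, subset to the cortex internally.
#' @param metaMaps named list of \linkS4class{MetaAnalyticMap} defined on
#'   cortex vertices (or matrix).
#' @param mesh a \linkS4class{SphereMesh} shared by both map sets.
#' @param nPerm number of spin permutations.
#' @param seed RNG seed.
#' @param alpha FDR level.
#' @param spin \code{"meta"} (default) spins the meta-analytic maps;
#'   \code{"target"} spins the targets (useful for calibration).
#' @param nulls optional precomputed \code{\link{spinNulls}} matrix to reuse
#'   across runs.
#' @param estimator p-value estimator, see \code{\link{permPvalue}}.
#' @return data.frame (decoding table) with columns segment, label, r, p, q,
#'   significant; rows sorted by segment then descending r.
#' @export
decode <- function(targetMaps, metaMaps, mesh, nPerm = 1000, seed = NULL,
                   alpha = 0.05, spin = c("meta", "target"), nulls = NULL,
                   estimator = c("fraction", "plus_one")) {
  spin <- match.arg(spin)
  estimator <- match.arg(estimator)
  cortex <- which(cortexMask(mesh))
  Tfull <- mapMatrix(targetMaps)
  Mfull <- mapMatrix(metaMaps)
  Tm <- if (nrow(Tfull) == length(cortex)) Tfull else Tfull[cortex, , drop = FALSE]
  Mm <- if (nrow(Mfull) == length(cortex)) Mfull else Mfull[cortex, , drop = FALSE]
  if (nrow(Tm) != nrow(Mm))
    stopUser("target and meta maps live on inconsistent vertex spaces")
  sds <- apply(Mm, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("excluding %d zero-variance meta map(s)", sum(sds == 0)))
    Mm <- Mm[, sds > 0, drop = FALSE]
  }
  if (is.null(nulls)) nulls <- spinNulls(mesh, nPerm = nPerm, seed = seed)
  nPerm <- nrow(nulls)
  rObs <- stats::cor(Tm, Mm)                   # k x m
  k <- ncol(Tm); m <- ncol(Mm)
  p <- matrix(NA_real_, k, m)
  if (spin == "meta") {
    for (j in seq_len(m)) {
      Mnull <- matrix(Mm[, j][t(nulls)], nrow = nrow(Mm))  # n x nPerm
      rNull <- stats::cor(Tm, Mnull)                       # k x nPerm
      for (s in seq_len(k))
        p[s, j] <- permPvalue(rObs[s, j], rNull[s, ], estimator)
    }
  } else {
    for (s in seq_len(k)) {
      Tnull <- matrix(Tm[, s][t(nulls)], nrow = nrow(Tm))
      rNull <- stats::cor(Mm, Tnull)                       # m x nPerm
      for (j in seq_len(m))
        p[s, j] <- permPvalue(rObs[s, j], rNull[j, ], estimator)
    }
  }
  adj <- fdrBH(as.numeric(p), alpha = alpha)
  tab <- data.frame(
    segment = rep(seq_len(k), times = m),
    label = rep(colnames(Mm), each = k),
    r = as.numeric(rObs),
    p = as.numeric(p),
    q = adj$q,
    significant = adj$significant,
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$segment, -tab$r, tab$label), ]
  rownames(tab) <- NULL
  tab
}

#' Correlation profile across segment solutions
#'
#' Per segment the top correlation against the map set, located at the
#' segment's peak coordinate on the gradient axis; summarized per k by the
#' mean and standard deviation of the per-segment maxima.
#'
#' @param decodings list of entries, each a list with elements \code{k},
#'   \code{table} (a decoding table from \code{\link{decode}}) and
#'   \code{peaks} (k-by-d peak matrix).
#' @return List with \code{points} (k, segment, x, topR, topLabel) and
#'   \code{summary} (k, meanTopR, sdTopR).
#' @export
correlationProfile <- function(decodings) {
  if (length(decodings) == 0) stopUser("need at least one segment solution")
  pts <- do.call(rbind, lapply(decodings, function(e) {
    tab <- e$table
    segs <- sort(unique(tab$segment))
    do.call(rbind, lapply(segs, function(s) {
      sub <- tab[tab$segment == s, ]
      top <- sub[which.max(sub$r), ]
      data.frame(k = e$k, segment = s, x = e$peaks[s, 1], topR = top$r,
                 topLabel = top$label, stringsAsFactors = FALSE)
    }))
  }))
  summ <- do.call(rbind, lapply(split(pts, pts$k), function(d) {
    data.frame(k = d$k[1], meanTopR = mean(d$topR),
               sdTopR = stats::sd(d$topR))
  }))
  rownames(summ) <- NULL
  list(points = pts, summary = summ)
}
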