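## Coordinate-based meta-analysis: study selection, modeled-activation (MA)
## maps, two-by-two chi-square meta maps, and LDA topic modeling.

#' Regular sampling grid for volumetric meta-analytic maps
#'
#' Isotropic grid of cell centers over a rectangular extent. Meta-analytic
#' maps can also be computed directly on surface vertices by passing vertex
#' coordinates as the cell centers.
#'
#' @param spacing isotropic cell spacing in mm.
#' @param extent numeric length-6 vector (xmin, xmax, ymin, ymax, zmin, zmax)
#'   in mm.
#' @return List with \code{centers} (cells-by-3 matrix), \code{spacing},
#'   \code{extent}.
#' @export
makeGrid <- function(spacing = 4,
                     extent = c(-72, 72, -72, 72, -72, 72)) {
  ax <- lapply(1:3, function(i)
    seq(extent[2 * i - 1] + spacing / 2, extent[2 * i], by = spacing))
  g <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  list(centers = g, spacing = spacing, extent = extent)
}

gridCenters <- function(grid) {
  if (is.matrix(grid)) grid else grid$centers
}

#' Modeled-activation map for one study
#'
#' Convolves the study's peak coordinates with a binary sphere of the given
#' radius and max-combines across peaks: a cell is active iff it lies within
#' the radius of at least one coordinate. Coordinates outside the grid extent
#' are clipped to it with a warning.
#'
#' @param coordinates m-by-3 matrix of peak coordinates (mm); zero rows give
#'   an all-zero map.
#' @param grid a grid from \code{\link{makeGrid}} or a bare cells-by-3 matrix
#'   of cell centers.
#' @param radius kernel radius in mm.
#' @return Integer 0/1 vector, one entry per grid cell.
#' @export
maMap <- function(coordinates, grid, radius = 10) {
  centers <- gridCenters(grid)
  out <- integer(nrow(centers))
  if (is.null(coordinates) || NROW(coordinates) == 0) return(out)
  coordinates <- matrix(as.numeric(as.matrix(coordinates)), ncol = 3)
  if (!is.matrix(grid) && !is.null(grid$extent)) {
    ext <- grid$extent
    lo <- ext[c(1, 3, 5)]; hi <- ext[c(2, 4, 6)]
    clipped <- pmax(pmin(coordinates, matrix(hi, nrow(coordinates), 3, byrow = TRUE)),
                    matrix(lo, nrow(coordinates), 3, byrow = TRUE))
    if (any(clipped != coordinates)) {
      warning("peak coordinate(s) outside grid extent; clipped")
      coordinates <- clipped
    }
  }
  r2 <- radius^2
  for (i in seq_len(nrow(coordinates))) {
    d2 <- rowSums((centers - matrix(coordinates[i, ], nrow(centers), 3,
                                    byrow = TRUE))^2)
    out[d2 <= r2] <- 1L
  }
  out
}

#' Modeled-activation maps for every study in a database
#'
#' @param db a \linkS4class{StudyDatabase}.
#' @param grid grid or vertex-center matrix (see \code{\link{maMap}}).
#' @param radius kernel radius in mm.
#' @return cells-by-studies binary matrix with study ids as column names.
#' @export
studyActivationMaps <- function(db, grid, radius = 10) {
  stopifnot(is(db, "StudyDatabase"))
  coords <- studyCoordinates(db)
  ids <- studyIds(db)
  centers <- gridCenters(grid)
  out <- matrix(0L, nrow(centers), length(ids), dimnames = list(NULL, ids))
  byStudy <- split(seq_len(nrow(coords)), coords$study)
  for (id in ids) {
    rows <- byStudy[[id]]
    if (!is.null(rows))
      out[, id] <- maMap(as.matrix(coords[rows, c("x", "y", "z")]), grid, radius)
  }
  out
}

#' Select the meta-analytic study sample for a term
#'
#' Studies whose TFIDF feature weight for the term exceeds the frequency
#' threshold, eliminating studies that use the term incidentally.
#'
#' @param db a \linkS4class{StudyDatabase}.
#' @param term term name from the database vocabulary.
#' @param threshold feature-weight threshold (default 0.001).
#' @return Character vector of selected study ids.
#' @export
selectByTerm <- function(db, term, threshold = 0.001) {
  feats <- studyFeatures(db)
  if (!term %in% colnames(feats))
    stopUser("term '%s' is not in the database vocabulary", term)
  sel <- studyIds(db)[feats[, term] > threshold]
  if (length(sel) == 0)
    stopUser("empty meta-analytic sample for term '%s' at threshold %g",
             term, threshold)
  sel
}

#' Select the meta-analytic study sample for a topic
#'
#' Studies whose p(topic | article) loading exceeds the frequency threshold.
#'
#' @param docTopic docs-by-topics matrix of p(topic | article) with document
#'   ids as row names.
#' @param topic topic index or name.
#' @param threshold probability threshold (default 0.05).
#' @return Character vector of selected document/study ids.
#' @export
selectByTopic <- function(docTopic, topic, threshold = 0.05) {
  w <- docTopic[, topic]
  ids <- rownames(docTopic)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(docTopic)))
  sel <- ids[w > threshold]
  if (length(sel) == 0)
    stopUser("empty meta-analytic sample for topic %s at threshold %g",
             as.character(topic), threshold)
  sel
}

#' Two-by-two chi-square meta-analysis across study maps
#'
#' For every grid cell, tabulates active/inactive against selected/unselected
#' studies and computes the Pearson chi-square statistic (no continuity
#' correction), reported as a z-like value \code{sqrt(chi2)} signed by the
#' direction of association, i.e. by
#' \code{sign(P(active | selected) - P(active | unselected))}. Cells with a
#' zero margin get statistic 0.
#'
#' @param selectedMaps cells-by-n1 binary matrix of MA maps in the selected
#'   sample.
#' @param unselectedMaps cells-by-n2 binary matrix for the remaining studies.
#' @param labels label(s) to attach to the resulting map.
#' @return A \linkS4class{MetaAnalyticMap}.
#' @export
chi2Meta <- function(selectedMaps, unselectedMaps, labels = "map") {
  selectedMaps <- as.matrix(selectedMaps)
  unselectedMaps <- as.matrix(unselectedMaps)
  if (nrow(selectedMaps) != nrow(unselectedMaps))
    stopUser("selected and unselected maps live on different grids")
  n1 <- ncol(selectedMaps); n2 <- ncol(unselectedMaps)
  if (n1 == 0 || n2 == 0) stopUser("both study groups must be nonempty")
  a <- rowSums(selectedMaps)          # active & selected
  c0 <- rowSums(unselectedMaps)       # active & unselected
  b <- n1 - a; d <- n2 - c0
  n <- n1 + n2
  m1 <- a + c0; m2 <- b + d           # active / inactive margins
  denom <- as.numeric(n1) * n2 * m1 * m2
  chi2 <- ifelse(denom == 0, 0, n * (a * d - b * c0)^2 / denom)
  sgn <- sign(a / n1 - c0 / n2)
  z <- sgn * sqrt(chi2)
  new("MetaAnalyticMap", labels = as.character(labels), values = as.numeric(z),
      chi2 = as.numeric(chi2), nSelected = as.integer(n1),
      nUnselected = as.integer(n2))
}

#' Fit an LDA topic model by collapsed Gibbs sampling
#'
#' Latent Dirichlet allocation over a token-count corpus, estimated with a
#' seeded collapsed Gibbs sampler (implemented in C++). Returns the two
#' distributions used downstream: p(word | topic) and p(topic | article),
#' each row-normalized from the final sampler state with the usual Dirichlet
#' smoothing.
#'
#' @param corpus a \linkS4class{Corpus}.
#' @param nTopics number of topics (default 200).
#' @param seed RNG seed; the same seed reproduces the model exactly.
#' @param iterations Gibbs sweeps.
#' @param alpha,beta symmetric Dirichlet hyperparameters for document-topic
#'   and topic-word distributions.
#' @return A \linkS4class{TopicModel}.
#' @export
fitTopics <- function(corpus, nTopics = 200, seed = NULL, iterations = 200,
                      alpha = 50 / nTopics, beta = 0.01) {
  stopifnot(is(corpus, "Corpus"))
  counts <- tokenCounts(corpus)
  if (sum(counts) == 0) stopUser("corpus is empty")
  if (ncol(counts) < nTopics)
    stopUser("vocabulary (%d) smaller than nTopics (%d)", ncol(counts), nTopics)
  # expand counts into token streams (document id, word id), 0-based for C++
  docIdx <- rep(seq_len(nrow(counts)) - 1L, times = rowSums(counts))
  wordIdx <- unlist(lapply(seq_len(nrow(counts)), function(d) {
    rep(seq_len(ncol(counts)) - 1L, times = counts[d, ])
  }), use.names = FALSE)
  fit <- withSeed(seed,
    ldaGibbs(docIdx, wordIdx, nrow(counts), ncol(counts),
             as.integer(nTopics), as.integer(iterations), alpha, beta))
  wt <- fit$topicWord + beta
  wt <- wt / rowSums(wt)
  colnames(wt) <- colnames(counts)
  dt <- fit$docTopic + alpha
  dt <- dt / rowSums(dt)
  rownames(dt) <- rownames(counts)
  new("TopicModel", wordTopic = wt, docTopic = dt, nTopics = as.integer(nTopics))
}

#' Top-word label of a topic
#'
#' Words sorted by descending p(word | topic); ties broken lexicographically.
#'
#' @param model a \linkS4class{TopicModel} or a named probability vector.
#' @param topic topic index (ignored when a bare vector is given).
#' @param nWords number of words to report (default 3).
#' @return Character vector of top words.
#' @export
topicLabel <- function(model, topic = 1, nWords = 3) {
  p <- if (is(model, "TopicModel")) wordTopic(model)[topic, ] else model
  if (nWords < 1 || nWords > length(p))
    stopUser("nWords must be between 1 and the vocabulary size")
  ord <- order(-p, names(p))
  names(p)[ord][seq_len(nWords)]
}

#' Term-based meta-analytic map set
#'
#' One chi-square meta-analytic map per vocabulary term with a nonempty,
#' non-exhaustive study selection at the frequency threshold; skipped terms
#' are reported in the \code{"skipped"} attribute.
#'
#' @param db a \linkS4class{StudyDatabase}.
#' @param grid grid or vertex-center matrix.
#' @param terms terms to map (default: full vocabulary).
#' @param threshold feature threshold (default 0.001).
#' @param radius MA kernel radius in mm.
#' @param studyMaps optional precomputed \code{\link{studyActivationMaps}}.
#' @return Named list of \linkS4class{MetaAnalyticMap}.
#' @export
buildTermMaps <- function(db, grid, terms = NULL, threshold = 0.001,
                          radius = 10, studyMaps = NULL) {
  if (is.null(terms)) terms <- colnames(studyFeatures(db))
  if (is.null(studyMaps)) studyMaps <- studyActivationMaps(db, grid, radius)
  ids <- studyIds(db)
  maps <- list(); skipped <- character(0)
  for (tm in terms) {
    sel <- tryCatch(selectByTerm(db, tm, threshold), error = function(e) NULL)
    if (is.null(sel) || length(sel) == length(ids)) {
      skipped <- c(skipped, tm); next
    }
    maps[[tm]] <- chi2Meta(studyMaps[, sel, drop = FALSE],
                           studyMaps[, setdiff(ids, sel), drop = FALSE],
                           labels = tm)
  }
  if (length(skipped))
    message(sprintf("skipped %d term(s) with empty or exhaustive selection",
                    length(skipped)))
  attr(maps, "skipped") <- skipped
  maps
}

#' Topic-based meta-analytic map set
#'
#' One chi-square meta-analytic map per topic, with the study sample selected
#' by thresholding p(topic | article) and the map labeled by the topic's top
#' words.
#'
#' @param db a \linkS4class{StudyDatabase}.
#' @param model a \linkS4class{TopicModel} (or a list with \code{docTopic} and
#'   \code{wordTopic} matrices) whose documents are the database studies.
#' @param grid grid or vertex-center matrix.
#' @param threshold p(topic | article) threshold (default 0.05).
#' @param nWords number of label words per topic.
#' @param radius MA kernel radius in mm.
#' @param studyMaps optional precomputed \code{\link{studyActivationMaps}}.
#' @return Named list of \linkS4class{MetaAnalyticMap} (names
#'   \code{topic1..topicT}).
#' @export
buildTopicMaps <- function(db, model, grid, threshold = 0.05, nWords = 3,
                           radius = 10, studyMaps = NULL) {
  dt <- if (is(model, "TopicModel")) docTopic(model) else model$docTopic
  wt <- if (is(model, "TopicModel")) wordTopic(model) else model$wordTopic
  if (is.null(rownames(dt))) rownames(dt) <- studyIds(db)
  if (is.null(studyMaps)) studyMaps <- studyActivationMaps(db, grid, radius)
  ids <- studyIds(db)
  maps <- list(); skipped <- character(0)
  for (t in seq_len(ncol(dt))) {
    nm <- paste0("topic", t)
    sel <- tryCatch(selectByTopic(dt, t, threshold), error = function(e) NULL)
    sel <- intersect(sel, ids)
    if (length(sel) == 0 || length(sel) == length(ids)) {
      skipped <- c(skipped, nm); next
    }
    lab <- topicLabel(wt[t, ], nWords = min(nWords, ncol(wt)))
    maps[[nm]] <- chi2Meta(studyMaps[, sel, drop = FALSE],
                           studyMaps[, setdiff(ids, sel), drop = FALSE],
                           labels = lab)
  }
  if (length(skipped))
    message(sprintf("skipped %d topic(s) with empty or exhaustive selection",
                    length(skipped)))
  attr(maps, "skipped") <- skipped
  maps
}
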