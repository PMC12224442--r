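## Semantic scoring of decoded labels: information content, TFIDF,
## expert-category classification, SNR, and report weights.

getCounts <- function(corpus) {
  if (is(corpus, "Corpus")) tokenCounts(corpus) else as.matrix(corpus)
}

resolveDocs <- function(counts, docIds) {
  if (is.character(docIds)) {
    miss <- setdiff(docIds, rownames(counts))
    if (length(miss)) stopUser("unknown document id(s): %s",
                               paste(utils::head(miss, 5), collapse = ", "))
  }
  counts[docIds, , drop = FALSE]
}

#' Information content of a word over a meta-analytic sample
#'
#' Per-document IC is \code{-log p(t, d)} (natural log) with
#' \code{p(t, d) = f(t, d) / N(d)}, the word's relative frequency among the
#' document's vocabulary tokens; the map-level value is the average across the
#' sampled documents. Documents where the word does not occur are skipped by
#' default (their IC is infinite); \code{smooth = TRUE} applies add-one
#' smoothing and keeps them.
#'
#' @param corpus a \linkS4class{Corpus} or counts matrix.
#' @param word vocabulary word.
#' @param docIds documents in the meta-analytic sample (ids or indices).
#' @param smooth use add-one smoothing instead of skipping absent documents.
#' @return Mean IC in nats (>= 0).
#' @export
icWord <- function(corpus, word, docIds, smooth = FALSE) {
  counts <- getCounts(corpus)
  if (!word %in% colnames(counts))
    stopUser("word '%s' not in corpus vocabulary", word)
  if (length(docIds) == 0) stopUser("document sample is empty")
  sub <- resolveDocs(counts, docIds)
  f <- sub[, word]
  N <- rowSums(sub)
  if (smooth) {
    p <- (f + 1) / (N + ncol(counts))
    return(mean(-log(p)))
  }
  keep <- f > 0
  if (!any(keep))
    stopUser("IC undefined: '%s' absent from all sampled documents", word)
  mean(-log(f[keep] / N[keep]))
}

#' Information content of a topic
#'
#' Sum of the individual ICs of the topic's top words. Top words with
#' undefined IC (absent from every sampled document) are skipped with a
#' warning.
#'
#' @param corpus a \linkS4class{Corpus} or counts matrix.
#' @param topWords character vector of the topic's top words.
#' @param docIds documents in the meta-analytic sample.
#' @param smooth passed to \code{\link{icWord}}.
#' @return Summed IC in nats.
#' @export
icTopic <- function(corpus, topWords, docIds, smooth = FALSE) {
  vals <- vapply(topWords, function(w) {
    tryCatch(icWord(corpus, w, docIds, smooth = smooth),
             error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(vals)))
    stopUser("IC undefined for every top word of the topic")
  if (anyNA(vals))
    warning(sprintf("skipping %d top word(s) with undefined IC", sum(is.na(vals))))
  sum(vals, na.rm = TRUE)
}

corpusIdf <- function(counts) {
  D <- nrow(counts)
  dt <- colSums(counts > 0)
  log((1 + D) / (1 + dt)) + 1
}

#' TFIDF of a word over a meta-analytic sample
#'
#' Term frequency is the raw count \code{f(t, d)}; the inverse document
#' frequency uses the smooth convention \code{ln((1 + D) / (1 + d_t)) + 1}
#' with D the corpus size and d_t the number of corpus documents containing
#' the word. The map-level value averages \code{tf * idf} over the sampled
#' documents (documents without the word contribute 0).
#'
#' @param corpus a \linkS4class{Corpus} or counts matrix (idf is computed on
#'   the whole corpus).
#' @param word vocabulary word.
#' @param docIds documents in the meta-analytic sample.
#' @return Mean TFIDF (>= 0).
#' @export
tfidfWord <- function(corpus, word, docIds) {
  counts <- getCounts(corpus)
  if (!word %in% colnames(counts))
    stopUser("word '%s' not in corpus vocabulary", word)
  if (length(docIds) == 0) stopUser("document sample is empty")
  idf <- corpusIdf(counts)[word]
  sub <- resolveDocs(counts, docIds)
  mean(sub[, word] * idf)
}

#' TFIDF of a topic
#'
#' Sum of the individual TFIDF values of the topic's top words.
#'
#' @inheritParams icTopic
#' @return Summed TFIDF.
#' @export
tfidfTopic <- function(corpus, topWords, docIds) {
  sum(vapply(topWords, function(w) tfidfWord(corpus, w, docIds), numeric(1)))
}

semanticCategories <- c("Anatomical", "Functional", "Clinical", "Non-specific")

#' Frequentist category model from expert annotations
#'
#' Converts per-word rater votes over the four categories (Anatomical,
#' Functional, Clinical, Non-specific) into p(category | word) by vote
#' proportion.
#'
#' @param annotations data.frame with columns \code{word} and \code{category}
#'   (one row per vote), or a words-by-categories vote-count matrix.
#' @return Words-by-categories probability matrix; rows sum to 1.
#' @export
categoryModel <- function(annotations) {
  if (is.data.frame(annotations)) {
    bad <- setdiff(unique(annotations$category), semanticCategories)
    if (length(bad)) stopUser("unknown category: %s", paste(bad, collapse = ", "))
    votes <- table(factor(annotations$word),
                   factor(annotations$category, levels = semanticCategories))
    votes <- matrix(as.numeric(votes), nrow(votes), ncol(votes),
                    dimnames = dimnames(votes))
  } else {
    votes <- as.matrix(annotations)[, semanticCategories, drop = FALSE]
  }
  tot <- rowSums(votes)
  if (any(tot == 0)) stopUser("every annotated word needs at least one vote")
  votes / tot
}

#' Classify a word by its category distribution
#'
#' The category with p(category | word) strictly greater than 0.5;
#' \code{"Non-specific"} when no category exceeds the threshold or the word is
#' unannotated (with a warning).
#'
#' @param model probability matrix from \code{\link{categoryModel}}.
#' @param word word to classify.
#' @return A category string.
#' @export
classifyWord <- function(model, word) {
  if (!word %in% rownames(model)) {
    warning(sprintf("word '%s' has no annotation; classified Non-specific", word))
    return("Non-specific")
  }
  p <- model[word, ]
  top <- which.max(p)
  if (p[top] > 0.5) colnames(model)[top] else "Non-specific"
}

#' Classify a topic by its weighted category scores
#'
#' Per category, sums p(category | word) weighted by p(word | topic); words
#' missing from the annotation model contribute their mass to Non-specific.
#' The topic takes the category whose score strictly exceeds 0.5, otherwise
#' \code{"Non-specific"}.
#'
#' @param model probability matrix from \code{\link{categoryModel}}.
#' @param wordDist named p(word | topic) vector for the topic.
#' @return A category string.
#' @export
classifyTopic <- function(model, wordDist) {
  wordDist <- wordDist / sum(wordDist)
  score <- stats::setNames(numeric(length(semanticCategories)),
                           semanticCategories)
  for (w in names(wordDist)) {
    if (w %in% rownames(model)) {
      score <- score + wordDist[[w]] * model[w, semanticCategories]
    } else {
      score["Non-specific"] <- score["Non-specific"] + wordDist[[w]]
    }
  }
  top <- which.max(score)
  if (score[top] > 0.5) names(score)[top] else "Non-specific"
}

#' Signal-to-noise ratio of a decoded label set
#'
#' Proportion of labels classified Functional to non-functional (Anatomical,
#' Clinical or Non-specific). With no non-functional labels the raw ratio is
#' infinite and flagged; the normalized SNR is the functional fraction, so
#' that \code{normalized = snr / (1 + snr)} whenever the ratio is finite.
#'
#' @param categories character vector of per-label categories.
#' @return List with \code{snr}, \code{normalizedSnr} and \code{infinite}
#'   flag.
#' @export
snr <- function(categories) {
  if (length(categories) == 0) stopUser("category list is empty")
  bad <- setdiff(unique(categories), semanticCategories)
  if (length(bad)) stopUser("unknown category: %s", paste(bad, collapse = ", "))
  nf <- sum(categories == "Functional")
  nn <- length(categories) - nf
  list(snr = if (nn == 0) Inf else nf / nn,
       normalizedSnr = nf / length(categories),
       infinite = nn == 0)
}

#' Word-cloud report weights from retained topic maps
#'
#' Bayes-inverts p(word | topic) under a uniform prior over the retained
#' topics to get p(topic | word), then weights each word by the sum over
#' topics of p(topic | word) times the topic map's correlation coefficient.
#' Filtering (dropping non-significant or non-functional topics) is expected
#' to have happened upstream.
#'
#' @param wordTopic retained-topics-by-words matrix of p(word | topic).
#' @param r correlation coefficient per retained topic.
#' @return Named numeric vector of word weights (words with zero mass under
#'   every retained topic are dropped).
#' @export
reportWeights <- function(wordTopic, r) {
  wordTopic <- as.matrix(wordTopic)
  if (nrow(wordTopic) != length(r))
    stopUser("need one correlation per retained topic")
  mass <- colSums(wordTopic)
  keep <- mass > 0
  pw <- wordTopic[, keep, drop = FALSE]
  # uniform topic prior cancels in the normalization
  ptGivenW <- t(t(pw) / colSums(pw))
  w <- as.numeric(r %*% ptGivenW)
  stats::setNames(w, colnames(pw))
}
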