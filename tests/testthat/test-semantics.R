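test_that("information content matches hand-computed values on the toy corpus", {
  # document "b b a": p(b) = 2/3, IC = -ln(2/3)
  corpus <- new("Corpus", counts = matrix(c(1L, 2L), 1,
                dimnames = list("d", c("a", "b"))))
  expect_equal(icWord(corpus, "b", "d"), -log(2 / 3), tolerance = 1e-12)
  expect_equal(icWord(corpus, "b", "d"), 0.4055, tolerance = 1e-4)
  # a word occupying the whole document has IC 0
  solo <- new("Corpus", counts = matrix(c(4L, 0L), 1,
              dimnames = list("d", c("a", "b"))))
  expect_equal(icWord(solo, "a", "d"), 0)
  expect_error(icWord(solo, "b", "d"), "absent")
  # rarer words carry more information
  tc <- toyCorpus()
  expect_gt(icWord(tc, "b", c("d1", "d2")), icWord(tc, "a", "d1") - 1e-12)
  # within a document, lower relative frequency means higher IC
  expect_gt(icWord(tc, "c", "d2"), icWord(tc, "b", "d2"))
  # averaging skips documents without the word
  expect_equal(icWord(tc, "a", c("d1", "d3")), -log(2 / 3), tolerance = 1e-12)
})

test_that("TFIDF follows the smooth-idf convention", {
  # D = 10 docs, word in 1, f = 2 -> 2 * (ln(11/2) + 1)
  counts <- matrix(0L, 10, 2, dimnames = list(paste0("d", 1:10), c("t", "u")))
  counts[1, "t"] <- 2L
  counts[, "u"] <- 1L
  corpus <- new("Corpus", counts = counts)
  expect_equal(tfidfWord(corpus, "t", "d1"), 2 * (log(11 / 2) + 1),
               tolerance = 1e-12)
  expect_equal(tfidfWord(corpus, "t", "d1"), 5.409, tolerance = 1e-3)
  # word in every document: idf floor of 1, TFIDF = mean tf
  expect_equal(tfidfWord(corpus, "u", c("d1", "d2")), 1)
  # absent documents contribute zero to the average
  expect_equal(tfidfWord(corpus, "t", c("d1", "d2")), (log(11 / 2) + 1),
               tolerance = 1e-12)
})

test_that("topic IC and TFIDF are sums over the top words", {
  tc <- toyCorpus()
  docs <- c("d1", "d2")
  expect_equal(icTopic(tc, c("a", "b"), docs),
               icWord(tc, "a", docs) + icWord(tc, "b", docs))
  expect_equal(icTopic(tc, "a", docs), icWord(tc, "a", docs))
  expect_equal(tfidfTopic(tc, c("a", "b", "c"), docs),
               tfidfWord(tc, "a", docs) + tfidfWord(tc, "b", docs) +
                 tfidfWord(tc, "c", docs))
  expect_warning(ic <- icTopic(tc, c("a", "f"), docs), "undefined")
  expect_equal(ic, icWord(tc, "a", docs))
})

test_that("category model and strict 0.5 classification rule", {
  votes <- data.frame(
    word = c(rep("move", 10), rep("split", 10), rep("acc", 10)),
    rater = rep(1:10, 3),
    category = c(rep("Functional", 10),
                 rep(c("Functional", "Clinical"), each = 5),
                 c(rep("Anatomical", 9), "Non-specific")))
  model <- categoryModel(votes)
  expect_equal(unname(rowSums(model)), rep(1, 3))
  expect_equal(model["move", "Functional"], 1)
  expect_equal(classifyWord(model, "move"), "Functional")
  expect_equal(classifyWord(model, "acc"), "Anatomical")
  # exact 0.5 does not pass the strict threshold
  expect_equal(classifyWord(model, "split"), "Non-specific")
  expect_warning(out <- classifyWord(model, "zzz"), "no annotation")
  expect_equal(out, "Non-specific")
  # 6/4 votes give (0.6, 0.4)
  v2 <- data.frame(word = "w", rater = 1:10,
                   category = c(rep("Functional", 6), rep("Clinical", 4)))
  m2 <- categoryModel(v2)
  expect_equal(unname(m2["w", c("Functional", "Clinical")]), c(0.6, 0.4))
})

test_that("topic classification weights word categories by p(word|topic)", {
  model <- rbind(w1 = c(0, 1, 0, 0), w2 = c(0, 1, 0, 0), w3 = c(0, 0, 1, 0))
  colnames(model) <- c("Anatomical", "Functional", "Clinical", "Non-specific")
  # scores: Functional = 0.6 + 0.3 = 0.9 -> Functional
  expect_equal(classifyTopic(model, c(w1 = 0.6, w2 = 0.3, w3 = 0.1)),
               "Functional")
  # 0.5/0.5 across two categories: no strict majority
  expect_equal(classifyTopic(model, c(w1 = 0.5, w3 = 0.5)), "Non-specific")
  # purely functional words
  expect_equal(classifyTopic(model, c(w1 = 0.7, w2 = 0.3)), "Functional")
  # unknown words contribute Non-specific mass
  expect_equal(classifyTopic(model, c(w1 = 0.4, unknown = 0.6)),
               "Non-specific")
})

test_that("SNR and its normalization are mutually consistent", {
  s <- snr(c("Functional", "Functional", "Functional", "Clinical"))
  expect_equal(s$snr, 3)
  expect_equal(s$normalizedSnr, 0.75)
  expect_equal(s$normalizedSnr, s$snr / (1 + s$snr))
  expect_equal(snr(c("Anatomical", "Clinical"))$snr, 0)
  allF <- snr(rep("Functional", 5))
  expect_true(allF$infinite)
  expect_equal(allF$normalizedSnr, 1)
  expect_error(snr(character(0)), "empty")
  set.seed(71)
  cats <- sample(c("Functional", "Clinical", "Anatomical"), 50, TRUE)
  s2 <- snr(cats)
  expect_equal(s2$normalizedSnr, s2$snr / (1 + s2$snr))
})

test_that("report weights Bayes-invert topic membership and scale by correlation", {
  wt <- rbind(t1 = c(shared = 0.5, only1 = 0.5, only2 = 0),
              t2 = c(shared = 0.5, only1 = 0, only2 = 0.5))
  w <- reportWeights(wt, r = c(0.4, 0.2))
  expect_equal(unname(w["shared"]), 0.3)      # 0.5*0.4 + 0.5*0.2
  expect_equal(unname(w["only1"]), 0.4)       # exclusive word: p(topic|word)=1
  expect_equal(unname(w["only2"]), 0.2)
  # single retained topic: weights proportional to r
  w1 <- reportWeights(wt[1, , drop = FALSE], r = 0.6)
  expect_equal(unname(w1), c(0.6, 0.6))
  expect_error(reportWeights(wt, r = 0.1), "one correlation")
})
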