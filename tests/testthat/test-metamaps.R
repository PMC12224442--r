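test_that("term selection thresholds feature weights as stated", {
  feats <- rbind(A = c(t1 = 0.5), B = c(t1 = 0.0005), C = c(t1 = 0))
  db <- new("StudyDatabase", studyIds = c("A", "B", "C"),
            coordinates = data.frame(study = "A", x = 0, y = 0, z = 0),
            features = feats)
  expect_equal(selectByTerm(db, "t1", 0.001), "A")
  expect_equal(sort(selectByTerm(db, "t1", 0)), c("A", "B"))
  expect_error(selectByTerm(db, "nope"), "vocabulary")
  expect_error(selectByTerm(db, "t1", 0.9), "empty")
})

test_that("topic selection thresholds p(topic|article)", {
  dt <- rbind(s1 = c(0.9, 0.1), s2 = c(0.04, 0.96), s3 = c(0.06, 0.94))
  expect_equal(selectByTopic(dt, 1, 0.05), c("s1", "s3"))
  expect_equal(sort(selectByTopic(dt, 1, 0)), c("s1", "s2", "s3"))
  expect_error(selectByTopic(dt, 1, 0.95), "empty")
})

test_that("MA maps match a brute-force sphere rasterization and max-combine", {
  grid <- makeGrid(spacing = 2, extent = c(-20, 20, -20, 20, -20, 20))
  focus <- matrix(c(1, -2, 3), 1)
  m <- maMap(focus, grid, radius = 10)
  oracle <- as.integer(sqrt(rowSums((grid$centers -
    matrix(focus, nrow(grid$centers), 3, byrow = TRUE))^2)) <= 10)
  expect_identical(m, oracle)
  # duplicate coordinates are idempotent under max-combine
  expect_identical(maMap(rbind(focus, focus), grid, radius = 10), m)
  # two distant foci: union of two disjoint spheres
  grid2 <- makeGrid(spacing = 4, extent = c(-60, 60, -30, 30, -30, 30))
  two <- rbind(c(-25, 0, 0), c(25, 0, 0))
  m2 <- maMap(two, grid2, radius = 10)
  mA <- maMap(two[1, , drop = FALSE], grid2, radius = 10)
  mB <- maMap(two[2, , drop = FALSE], grid2, radius = 10)
  expect_identical(m2, pmax(mA, mB))
  expect_equal(sum(mA * mB), 0)
  # zero coordinates: all-zero map; out-of-grid coordinates clip with warning
  expect_equal(sum(maMap(NULL, grid)), 0)
  expect_warning(maMap(matrix(c(500, 0, 0), 1), grid), "clipped")
})

test_that("chi-square meta map equals the textbook 2x2 statistic", {
  # perfect association: a=10, b=0, c=0, d=10 -> chi2 = 20, positive
  sel <- matrix(1L, 1, 10); uns <- matrix(0L, 1, 10)
  m <- chi2Meta(sel, uns)
  expect_equal(m@chi2, 20)
  expect_equal(mapValues(m), sqrt(20))
  # identical activation proportions: statistic 0
  m0 <- chi2Meta(matrix(c(1L, 0L), 1, 2), matrix(c(1L, 0L), 1, 2))
  expect_equal(mapValues(m0), 0)
  # swapping groups flips every sign
  set.seed(41)
  S <- matrix(rbinom(50 * 8, 1, 0.4), 50)
  U <- matrix(rbinom(50 * 12, 1, 0.2), 50)
  expect_equal(mapValues(chi2Meta(S, U)), -mapValues(chi2Meta(U, S)))
  # matches stats::chisq.test without continuity correction per cell
  mm <- chi2Meta(S, U)
  for (cell in c(1, 7, 23, 50)) {
    tab <- rbind(c(sum(S[cell, ]), ncol(S) - sum(S[cell, ])),
                 c(sum(U[cell, ]), ncol(U) - sum(U[cell, ])))
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      oracle <- suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)
      expect_equal(mm@chi2[cell], unname(oracle), tolerance = 1e-9)
    }
  }
  expect_error(chi2Meta(matrix(1L, 2, 3), matrix(1L, 3, 3)), "grids")
})

test_that("LDA fitting is seeded, normalized, and recovers planted topics", {
  # two disjoint-vocabulary document groups
  vocab <- c(paste0("x", 1:6), paste0("y", 1:6))
  counts <- matrix(0L, 20, 12, dimnames = list(paste0("d", 1:20), vocab))
  set.seed(42)
  counts[1:10, 1:6] <- matrix(rpois(60, 8), 10)
  counts[11:20, 7:12] <- matrix(rpois(60, 8), 10)
  corpus <- new("Corpus", counts = counts)
  fit <- fitTopics(corpus, nTopics = 2, seed = 7, iterations = 100)
  expect_equal(rowSums(wordTopic(fit)), c(1, 1), tolerance = 1e-6)
  expect_equal(unname(rowSums(docTopic(fit))), rep(1, 20), tolerance = 1e-6)
  top1 <- topicLabel(fit, 1, 3); top2 <- topicLabel(fit, 2, 3)
  firstChar <- function(w) substr(w, 1, 1)
  expect_length(unique(vapply(top1, firstChar, character(1))), 1)
  expect_length(unique(vapply(top2, firstChar, character(1))), 1)
  expect_false(firstChar(top1[1]) == firstChar(top2[1]))
  # determinism under the same seed
  fit2 <- fitTopics(corpus, nTopics = 2, seed = 7, iterations = 100)
  expect_identical(wordTopic(fit), wordTopic(fit2))
  expect_error(fitTopics(corpus, nTopics = 50), "smaller")
})

test_that("topic labels sort by probability with lexicographic ties", {
  p <- c(a = 0.5, b = 0.3, c = 0.2)
  expect_equal(topicLabel(p, nWords = 2), c("a", "b"))
  pt <- c(b = 0.4, a = 0.4, c = 0.2)
  expect_equal(topicLabel(pt, nWords = 2), c("a", "b"))
  expect_error(topicLabel(p, nWords = 9), "vocabulary")
})

test_that("map-set builders produce one labeled map per usable term/topic", {
  # focal (cap-sampled) database so each topic has one planted focus
  w <- synthDatabase(nStudies = 120, nTopics = 6, vocabSize = 90, seed = 6,
                     mesh = synthSphere(400, seed = 61))
  cortex <- which(cortexMask(w$mesh))
  centers <- meshCoordinates(w$mesh)[cortex, ]
  sm <- studyActivationMaps(w$db, centers, radius = 10)
  model <- list(docTopic = w$truth$docTopic, wordTopic = w$truth$wordTopic)
  tmaps <- buildTopicMaps(w$db, model, centers, studyMaps = sm)
  expect_length(tmaps, ncol(w$truth$docTopic))
  expect_true(all(vapply(tmaps, function(m) length(mapLabels(m)), 1L) == 3))
  # planted spatial structure: each topic map's |statistic| peak lies within
  # one kernel radius of the planted center for most topics
  hit <- vapply(seq_along(tmaps), function(t) {
    peak <- centers[which.max(abs(mapValues(tmaps[[t]]))), ]
    sqrt(sum((peak - w$truth$topicCenters[t, ])^2)) <= 20
  }, logical(1))
  expect_gte(mean(hit), 0.8)
  # term maps for signature words
  sig <- vapply(w$truth$signatureWords, `[`, character(1), 1)
  termMaps <- buildTermMaps(w$db, centers, terms = sig, studyMaps = sm)
  expect_lte(length(termMaps), length(sig))
  expect_true(all(names(termMaps) %in% sig))
})
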