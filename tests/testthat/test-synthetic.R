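test_that("synthetic connectome is a valid, seed-deterministic r-matrix", {
  sim <- synthConnectome(100, seed = 81)
  C <- connectivityValues(sim$connectome)
  expect_equal(valueKind(sim$connectome), "r")
  expect_equal(C, t(C))
  expect_true(all(C >= -1 & C <= 1))
  expect_equal(diag(C), rep(1, 100))
  # adjacent latent positions are near 1 without noise
  clean <- synthConnectome(100, noiseSd = 0, seed = 81)
  t0 <- clean$truth$latentAxis
  ij <- order(t0)[1:2]
  expect_equal(connectivityValues(clean$connectome)[ij[1], ij[2]],
               exp(-abs(t0[ij[1]] - t0[ij[2]]) / 0.1), tolerance = 1e-12)
  # bitwise determinism
  sim2 <- synthConnectome(100, seed = 81)
  expect_identical(C, connectivityValues(sim2$connectome))
  expect_error(synthConnectome(100, noiseSd = -1), "noiseSd")
  expect_error(synthConnectome(10), "50")
})

test_that("fibonacci sphere is quasi-uniform with the requested medial cap", {
  mesh <- synthSphere(800, medialFraction = 0.1, seed = 82)
  XYZ <- meshCoordinates(mesh)
  expect_equal(sqrt(rowSums(XYZ^2)), rep(100, 800), tolerance = 1e-9)
  expect_equal(mean(!cortexMask(mesh)), 0.1, tolerance = 0.05)
  # nearest-neighbour spacing coefficient of variation below 0.2
  D <- as.matrix(dist(XYZ))
  diag(D) <- Inf
  nn <- apply(D, 1, min)
  expect_lt(sd(nn) / mean(nn), 0.2)
  # the medial wall is a contiguous cap: its vertices are the top-x cap
  medial <- which(!cortexMask(mesh))
  expect_true(all(XYZ[medial, 1] > max(XYZ[-medial, 1]) - 1e-9))
  expect_error(synthSphere(100, medialFraction = 1), "medialFraction")
})

test_that("synthetic database plants coherent topics, features and coordinates", {
  out <- synthDatabase(nStudies = 80, nTopics = 5, vocabSize = 50, seed = 83)
  db <- out$db; corpus <- out$corpus
  expect_s4_class(db, "StudyDatabase")
  feats <- studyFeatures(db)
  counts <- tokenCounts(corpus)
  expect_true(all(feats >= 0))
  expect_true(all(feats[counts == 0] == 0))
  expect_true(all(feats[counts > 0] > 0))
  # planted selection: studies with positive feature are exactly recovered
  wordd <- colnames(feats)[5]
  planted <- studyIds(db)[counts[, wordd] > 0]
  expect_setequal(selectByTerm(db, wordd, threshold = 0), planted)
  # coordinates cluster near the dominant topic's center
  dt <- out$truth$docTopic
  dom <- apply(dt, 1, which.max)
  strong <- which(apply(dt, 1, max) > 0.9)[1:5]
  coords <- studyCoordinates(db)
  for (s in strong) {
    pts <- coords[coords$study == studyIds(db)[s], c("x", "y", "z")]
    ctr <- out$truth$topicCenters[dom[s], ]
    dmed <- median(sqrt(rowSums((as.matrix(pts) -
      matrix(ctr, nrow(pts), 3, byrow = TRUE))^2)))
    expect_lt(dmed, 40)
  }
  # determinism
  out2 <- synthDatabase(nStudies = 80, nTopics = 5, vocabSize = 50, seed = 83)
  expect_identical(studyFeatures(out2$db), feats)
  expect_error(synthDatabase(nTopics = 10, vocabSize = 20), "5 \\* nTopics")
})

test_that("LDA refit on synthetic corpus recovers planted word groups", {
  out <- synthDatabase(nStudies = 150, nTopics = 4, vocabSize = 60,
                       seed = 84, tokensPerDoc = 200)
  fit <- fitTopics(out$corpus, nTopics = 4, seed = 85, iterations = 150)
  # match each fitted topic to the planted topic sharing most top words
  topFit <- lapply(1:4, function(t) topicLabel(fit, t, 10))
  topTrue <- lapply(1:4, function(t)
    topicLabel(out$truth$wordTopic[t, ], nWords = 10))
  overlap <- sapply(topFit, function(f)
    max(sapply(topTrue, function(tr) length(intersect(f, tr)))))
  expect_gte(mean(overlap / 10), 0.6)
})

test_that("synthetic annotations behave as planted", {
  ann <- synthAnnotations(sprintf("w%02d", 1:40), functionalFraction = 0.5,
                          agreement = 1, seed = 86)
  model <- categoryModel(ann$votes)
  recovered <- vapply(rownames(model), function(w) classifyWord(model, w),
                      character(1))
  expect_equal(unname(recovered[names(ann$truth)]), unname(ann$truth))
  # near-chance agreement leaves most words Non-specific under the 0.5 rule
  low <- synthAnnotations(sprintf("w%02d", 1:100), agreement = 0.25, seed = 87)
  lowModel <- categoryModel(low$votes)
  lowCats <- vapply(rownames(lowModel), function(w) classifyWord(lowModel, w),
                    character(1))
  expect_gt(mean(lowCats == "Non-specific"), 0.5)
  expect_error(synthAnnotations("w", agreement = 0.1), "agreement")
})

test_that("functional fraction is recovered at scale", {
  ann <- synthAnnotations(sprintf("w%04d", 1:2000), functionalFraction = 0.5,
                          agreement = 0.9, seed = 88)
  model <- categoryModel(ann$votes)
  cats <- vapply(rownames(model), function(w) classifyWord(model, w),
                 character(1))
  expect_equal(mean(cats == "Functional"), 0.5, tolerance = 0.05)
})

test_that("coupled world is reproducible from its root seed", {
  w1 <- synthWorld(nVertices = 200, nStudies = 40, nTopics = 4,
                   vocabSize = 40, seed = 89)
  w2 <- synthWorld(nVertices = 200, nStudies = 40, nTopics = 4,
                   vocabSize = 40, seed = 89)
  expect_identical(connectivityValues(w1$connectome),
                   connectivityValues(w2$connectome))
  expect_identical(studyFeatures(w1$db), studyFeatures(w2$db))
  expect_identical(w1$annotations, w2$annotations)
  # latent axis is the cortex z-axis, so end topics anchor the ends
  ctr <- w1$truth$topicCenters
  expect_lt(ctr[1, 3], ctr[4, 3])
})
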