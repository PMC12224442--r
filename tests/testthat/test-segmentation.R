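test_that("percentile segmentation balances populations at the stated boundaries", {
  s <- segmentPct(1:10, 2)
  expect_equal(segmentBoundaries(s), 5.5)
  expect_equal(segmentLabels(s), rep(1:2, each = 5))
  s5 <- segmentPct(1:10, 5)
  expect_equal(segmentBoundaries(s5), c(2.8, 4.6, 6.4, 8.2))
  expect_equal(as.numeric(table(segmentLabels(s5))), rep(2, 5))
  # populations equal +-1 regardless of the value distribution
  set.seed(21)
  for (k in c(2, 3, 7, 13)) {
    v <- rexp(257)^2
    tab <- table(segmentLabels(segmentPct(v, k)))
    expect_lte(max(tab) - min(tab), 1)
  }
  expect_error(segmentPct(rep(1, 10), 3), "distinct")
})

test_that("1-D k-means separates separable data and beats random restarts", {
  v <- c(0, 0, 0, 10, 10, 10)
  s <- segmentKmeans(v, 2, seed = 1)
  expect_equal(segmentLabels(s), c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_equal(segmentAnchors(s)[, 1], c(0, 10))
  expect_error(segmentKmeans(rep(3, 10), 2), "distinct")
  # SSE no worse than a 50-restart random-start oracle
  set.seed(4)
  v2 <- c(rnorm(40, 0), rnorm(40, 3), rnorm(40, 9))
  s3 <- segmentKmeans(v2, 3, seed = 2)
  sse <- s3@extras$totWithinss
  oracle <- min(vapply(1:50, function(i) {
    suppressWarnings(stats::kmeans(v2, centers = sample(v2, 3),
                                   iter.max = 100))$tot.withinss
  }, numeric(1)))
  expect_lte(sse, oracle + 1e-8)
})

test_that("KDE segmentation places boundaries at density minima", {
  set.seed(8)
  v <- c(rnorm(150, 0), rnorm(150, 10))
  s <- segmentKde(v, 2)
  b <- segmentBoundaries(s)
  expect_length(b, 1)
  expect_gt(b, 3); expect_lt(b, 7)
  # boundary sits at a local minimum of a dense-grid density oracle
  d <- density(v, bw = s@extras$bandwidth, n = 4096)
  i <- which.min(abs(d$x - b))
  win <- d$y[max(1, i - 60):min(length(d$y), i + 60)]
  expect_lte(d$y[i], min(win) + 1e-3 * diff(range(d$y)))
  # unimodal data still yield exactly one boundary for k=2 (small bandwidth)
  u <- rnorm(300)
  s2 <- segmentKde(u, 2)
  expect_length(segmentBoundaries(s2), 1)
  expect_equal(sort(unique(segmentLabels(s2))), 1:2)
  # unreachable k errors with achievable counts reported
  expect_error(segmentKde(c(rep(0, 60), rep(1, 60)) + rnorm(120, sd = 1e-3), 40),
               "tuning failed|empty segment")
})

test_that("segmentations satisfy the partition/monotonicity/boundary contract", {
  set.seed(10)
  v <- c(rnorm(200, -1.5), rnorm(250, 0.5, 1.2), rnorm(150, 3))
  for (k in c(2, 5, 9, 17)) {
    segs <- list(segmentPct(v, k), segmentKmeans(v, k, seed = k),
                 segmentKde(v, k))
    for (s in segs) {
      lab <- segmentLabels(s)
      expect_equal(sort(unique(lab)), seq_len(k))
      expect_length(segmentBoundaries(s), k - 1)
      expect_false(is.unsorted(segmentBoundaries(s), strictly = TRUE))
      # monotone along the axis
      expect_false(is.unsorted(lab[order(v)]))
    }
  }
})

test_that("silhouette map equals the brute-force formula and flags boundary points", {
  set.seed(12)
  X <- matrix(rnorm(80 * 2), 80)
  lab <- sample(1:3, 80, replace = TRUE)
  expect_equal(silhouetteMap(X, lab), silhouetteOracle(X, lab),
               tolerance = 1e-10)
  # tight, far clusters: all coefficients near 1
  Y <- rbind(matrix(rnorm(60, sd = 0.01), 30), matrix(rnorm(60, 50, 0.01), 30))
  lab2 <- rep(1:2, each = 30)
  expect_true(all(silhouetteMap(Y, lab2) > 0.99))
  # a point equidistant between clusters scores near 0
  Z <- matrix(c(0, 0, 0, 1, 10, 0, 10, 1, 5, 0.5), ncol = 2, byrow = TRUE)
  lab3 <- c(1, 1, 2, 2, 1)
  expect_lt(abs(silhouetteMap(Z, lab3)[5]), 0.1)
  expect_error(silhouetteMap(X, rep(1, 80)), "single cluster")
})

test_that("cluster quality metrics match brute-force oracles", {
  set.seed(13)
  for (rep in 1:3) {
    X <- matrix(rnorm(120 * 2), 120)
    lab <- sample(1:4, 120, replace = TRUE)
    q <- clusterQuality(X, lab)
    expect_equal(q$meanSilhouette, mean(silhouetteOracle(X, lab)),
                 tolerance = 1e-10)
    expect_equal(q$varianceRatio, chOracle(X, lab), tolerance = 1e-10)
    expect_equal(q$clusterSeparation, dbOracle(X, lab), tolerance = 1e-10)
  }
  # well-separated clusters: high variance ratio, low separation
  Y <- rbind(matrix(rnorm(40, 0, 0.05), 20), matrix(rnorm(40, 20, 0.05), 20))
  lab2 <- rep(1:2, each = 20)
  q2 <- clusterQuality(Y, lab2)
  expect_gt(q2$varianceRatio, 1e4)
  expect_lt(q2$clusterSeparation, 0.05)
  # random labels on structureless points: mean silhouette near 0
  sil <- mean(replicate(10, {
    X <- matrix(rnorm(100), 50)
    mean(silhouetteMap(X, sample(1:2, 50, TRUE)))
  }))
  expect_lt(abs(sil), 0.05)
})

test_that("multidimensional k-means recovers separable blobs in 2, 4 and 7 dims", {
  set.seed(14)
  for (d in c(2, 4, 7)) {
    centers <- matrix(rnorm(3 * d, sd = 10), 3)
    X <- do.call(rbind, lapply(1:3, function(j)
      matrix(rnorm(30 * d, sd = 0.2), 30) +
        matrix(centers[j, ], 30, d, byrow = TRUE)))
    s <- multidimCluster(X, 3, seed = d)
    truth <- rep(1:3, each = 30)
    expect_equal(nmi(segmentLabels(s), truth), 1)
    expect_equal(dim(segmentAnchors(s)), c(3L, d))
    expect_length(segmentBoundaries(s), 0)
  }
  expect_error(multidimCluster(matrix(1, 10, 2), 3), "distinct")
})

test_that("NMI is 1 for relabelings and near 0 for independent labelings", {
  a <- c(1, 1, 2, 2, 3, 3)
  expect_equal(nmi(a, a), 1)
  expect_equal(nmi(a, c(3, 3, 1, 1, 2, 2)), 1)   # permuted ids
  set.seed(15)
  x <- sample(1:4, 10000, TRUE)
  y <- sample(1:4, 10000, TRUE)
  expect_lt(nmi(x, y), 0.01)
  expect_error(nmi(integer(0), integer(0)), "nonempty")
  # cross-check against an independent graph-library implementation
  skip_if_not_installed("igraph")
  b <- sample(1:3, 500, TRUE); c2 <- sample(1:5, 500, TRUE)
  expect_equal(nmi(b, c2), igraph::compare(b, c2, method = "nmi"),
               tolerance = 1e-10)
})

test_that("three approaches over k=2..32 yield 93 segmentation solutions", {
  set.seed(16)
  v <- c(rnorm(160, -2), rnorm(180, 0.5, 1.3), rnorm(160, 3.5))
  solutions <- 0L
  for (k in 2:32) {
    for (m in c("PCT", "KMeans", "KDE")) {
      s <- switch(m, PCT = segmentPct(v, k),
                  KMeans = segmentKmeans(v, k, seed = k), KDE = segmentKde(v, k))
      expect_equal(nSegments(s), k)
      solutions <- solutions + 1L
    }
  }
  expect_equal(solutions, 93L)
})
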