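# Brute-force oracles, independent of the package's implementations.

pointMat <- function(x) if (is.matrix(x)) x else matrix(x, ncol = 1)

euclid <- function(a, b) sqrt(sum((a - b)^2))

# Silhouette by the direct pairwise-distance formula; singleton clusters 0.
silhouetteOracle <- function(X, labels) {
  X <- pointMat(X)
  n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(vapply(setdiff(own, i), function(j) euclid(X[i, ], X[j, ]),
                     numeric(1)))
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l) {
      mean(vapply(which(labels == l), function(j) euclid(X[i, ], X[j, ]),
                  numeric(1)))
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# Calinski-Harabasz via explicit scatter sums.
chOracle <- function(X, labels) {
  X <- pointMat(X)
  n <- nrow(X); ks <- unique(labels); k <- length(ks)
  grand <- colMeans(X)
  B <- 0; W <- 0
  for (l in ks) {
    Xi <- X[labels == l, , drop = FALSE]
    ci <- colMeans(Xi)
    B <- B + nrow(Xi) * sum((ci - grand)^2)
    for (r in seq_len(nrow(Xi))) W <- W + sum((Xi[r, ] - ci)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

# Davies-Bouldin via explicit per-cluster dispersions.
dbOracle <- function(X, labels) {
  X <- pointMat(X)
  ks <- unique(labels); k <- length(ks)
  cen <- lapply(ks, function(l) colMeans(X[labels == l, , drop = FALSE]))
  disp <- vapply(seq_along(ks), function(i) {
    Xi <- X[labels == ks[i], , drop = FALSE]
    mean(vapply(seq_len(nrow(Xi)), function(r) euclid(Xi[r, ], cen[[i]]),
                numeric(1)))
  }, numeric(1))
  mean(vapply(seq_len(k), function(i) {
    max(vapply(seq_len(k)[-i], function(j)
      (disp[i] + disp[j]) / euclid(cen[[i]], cen[[j]]), numeric(1)))
  }, numeric(1)))
}

# Benjamini-Hochberg step-up, spelled out.
bhOracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[ord[i]] * m / i)
    q[ord[i]] <- val
    prev <- val
  }
  pmin(q, 1)
}

# Moran-type spatial autocorrelation with inverse-distance weights.
moranStat <- function(values, coords) {
  n <- length(values)
  D <- as.matrix(dist(coords))
  W <- 1 / (D + diag(n))
  diag(W) <- 0
  zc <- values - mean(values)
  (n / sum(W)) * sum(W * outer(zc, zc)) / sum(zc^2)
}

smallWorld <- function(seed = 5, nVertices = 400, nStudies = 120,
                       nTopics = 6, vocabSize = 90) {
  synthWorld(nVertices = nVertices, nStudies = nStudies, nTopics = nTopics,
             vocabSize = vocabSize, seed = seed)
}

toyCorpus <- function() {
  # 5 documents over a 6-word vocabulary; counts chosen for hand arithmetic
  counts <- rbind(
    d1 = c(a = 2L, b = 1L, c = 0L, d = 0L, e = 0L, f = 0L),
    d2 = c(a = 1L, b = 2L, c = 1L, d = 0L, e = 0L, f = 0L),
    d3 = c(a = 0L, b = 0L, c = 3L, d = 1L, e = 0L, f = 0L),
    d4 = c(a = 1L, b = 0L, c = 0L, d = 2L, e = 1L, f = 0L),
    d5 = c(a = 0L, b = 0L, c = 0L, d = 0L, e = 2L, f = 2L))
  new("Corpus", counts = counts)
}
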