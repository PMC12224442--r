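## Internal helpers.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. A NULL seed leaves the RNG alone.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministically derive a stage seed from a root seed; stays below 2^31.
deriveSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

# FNV-1a style string hash, hex encoded; used for config fingerprints.
stringHash <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

# Euclidean distances from each row of X (n x d) to a single point p.
distToPoint <- function(X, p) {
  X <- as.matrix(X)
  sqrt(rowSums((X - matrix(p, nrow(X), length(p), byrow = TRUE))^2))
}

# Full cross-distance matrix between rows of A and rows of B.
crossDist <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

asPointMatrix <- function(values) {
  if (is.matrix(values)) values else matrix(as.numeric(values), ncol = 1)
}

stopUser <- function(...) stop(sprintf(...), call. = FALSE)
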