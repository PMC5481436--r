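# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards. seed = NULL uses the current stream.
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive k reproducible sub-seeds from one master seed (kept < 2^31).
deriveSeeds <- function(seed, k) {
  if (is.null(seed)) return(rep(list(NULL), k))
  withSeed(seed, as.list(sample.int(.Machine$integer.max %/% 2L, k)))
}

# Squared Euclidean distances between rows of P[idx1, ] and rows of P[idx2, ].
rowSqDist <- function(P, idx1, idx2) {
  X <- P[idx1, , drop = FALSE]
  Y <- P[idx2, , drop = FALSE]
  d <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  d[d < 0] <- 0  # numerical negatives
  d
}

# sample() without the length-1 surprise.
sampleVec <- function(x, size, replace = FALSE, prob = NULL) {
  if (length(x) == 1L && !replace && size == 1L) return(x)
  if (length(x) == 1L) return(rep(x, size))
  sample(x, size, replace = replace, prob = prob)
}
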