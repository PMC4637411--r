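## Internal helpers shared across modules.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All seeded operations in the package go
# through this so that a run never perturbs (nor depends on) ambient RNG
# state.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a per-stage seed from a global one, kept below 2^31.
deriveSeed <- function(seed, stage) {
  (as.integer(seed) * 48271 + stage * 1009) %% 2147483629L
}

# Canonical list of unordered pairs i < j over N nodes, as an npairs x 2
# integer matrix in column-major combn order.
canonicalPairs <- function(N) {
  if (N < 2L) return(matrix(integer(0), 0L, 2L))
  t(utils::combn(N, 2L))
}

# Row index of pair (i, j), i < j, in canonicalPairs(N).
pairRow <- function(N, i, j) {
  stopifnot(i < j)
  (i - 1L) * N - i * (i - 1L) / 2L + (j - i)
}

# Scatter a per-pair vector into a symmetric N x N matrix, zero diagonal.
pairsToMatrix <- function(values, pairs, N) {
  M <- matrix(0, N, N)
  M[cbind(pairs[, 1], pairs[, 2])] <- values
  M[cbind(pairs[, 2], pairs[, 1])] <- values
  M
}

fmtNum <- function(x) formatC(x, digits = 17, format = "g")
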