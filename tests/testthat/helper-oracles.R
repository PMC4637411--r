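# Independent oracles and small fixture builders used across the suite.
# Everything here recomputes expected values from first principles, without
# going through the package's own code paths under test.

# Classical Gram-Schmidt orthonormalization of the monomials on {0..Q-1},
# written as an explicit loop (independent of the QR-based implementation).
gramSchmidtBasis <- function(Q) {
  x <- 0:(Q - 1)
  V <- outer(x, 0:(Q - 1), function(a, p) as.numeric(a)^p)
  B <- matrix(0, Q, Q)
  for (k in seq_len(Q)) {
    v <- V[, k]
    # two projection passes: the Vandermonde columns are ill-conditioned at
    # moderate Q and a single classical pass loses orthogonality
    for (pass in 1:2) {
      if (k > 1) for (j in seq_len(k - 1)) v <- v - sum(v * B[, j]) * B[, j]
    }
    # normalizing the residual keeps the leading coefficient positive
    v <- v / sqrt(sum(v^2))
    B[, k] <- v
  }
  t(B)  # row k+1 = Phi_k on the grid
}

# Two-node Boltzmann pair table by direct enumeration: P(x, y) proportional
# to exp(-H(x, y)) with H built from the block and an independently
# orthonormalized basis (verbatim expansion, (0,0) dropped).
twoNodeOracleTable <- function(block, Q) {
  Phi <- gramSchmidtBasis(Q)
  H <- matrix(0, Q, Q)
  for (x in 0:(Q - 1)) for (y in 0:(Q - 1)) {
    h <- 0
    for (k in 1:(Q - 1))
      h <- h + (block[k + 1, 1] * Phi[k + 1, x + 1] +
                block[1, k + 1] * Phi[k + 1, y + 1]) / Q
    for (k in 0:(Q - 1)) for (l in 0:(Q - 1))
      if (k > 0 || l > 0)
        h <- h + block[k + 1, l + 1] * Phi[k + 1, x + 1] * Phi[l + 1, y + 1]
    H[x + 1, y + 1] <- h
  }
  P <- exp(-H)
  P / sum(P)
}

# All set partitions of n elements (restricted-growth strings); the
# brute-force search space for the modularity oracle.
allPartitions <- function(n) {
  res <- list()
  rec <- function(a, m) {
    if (length(a) == n) { res[[length(res) + 1]] <<- a; return() }
    for (v in 1:(m + 1)) rec(c(a, v), max(m, v))
  }
  rec(1L, 1L)
  res
}

bruteForceModularity <- function(W) {
  max(vapply(allPartitions(nrow(W)), function(p) weightedModularity(W, p), 0))
}

# Mann-Whitney AUC of scores separating positives from negatives.
rankAUC <- function(scores, positive) {
  r <- rank(scores)
  nPos <- sum(positive); nNeg <- sum(!positive)
  (sum(r[positive]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

# Random observation set with iid uniform states.
randomObservationSet <- function(M, N, Q, seed) {
  withr::with_seed(seed, {
    S <- matrix(sample(0:(Q - 1), M * N, replace = TRUE), M, N)
    new("ObservationSet", states = S, Q = as.integer(Q),
        provenance = "test-random")
  })
}

# Empirical frequency tables of an observation set (the histogram oracle).
empiricalSingleTable <- function(D, i) {
  tabulate(stateMatrix(D)[, i] + 1L, nStates(D)) / nrow(stateMatrix(D))
}
empiricalPairTable <- function(D, i, j) {
  S <- stateMatrix(D); Q <- nStates(D)
  t0 <- matrix(0, Q, Q)
  idx <- table(factor(S[, i], levels = 0:(Q - 1)),
               factor(S[, j], levels = 0:(Q - 1)))
  t0 + as.matrix(idx) / nrow(S)
}

# Canonical i < j pair ordering used by the package's pair-indexed slots.
canonicalPairsForTest <- function(N) t(utils::combn(N, 2L))

# Tiny affiliation fixture from a list of activity membership vectors.
affFromActivities <- function(activities, N) {
  A <- matrix(0, N, length(activities))
  for (mu in seq_along(activities)) A[activities[[mu]], mu] <- 1
  affiliationMatrix(A)
}
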