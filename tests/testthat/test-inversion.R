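test_that("moments reproduce constant and degenerate-weight cases", {
  b <- chebyshevBasis(2)
  S <- matrix(1L, 50, 3)
  D <- new("ObservationSet", states = S, Q = 2L, provenance = "const")
  mom <- empiricalMoments(D, b)
  expect_equal(mom@first[, 1], rep(basisValues(b)[2, 2], 3),
               tolerance = 1e-12)
  expect_equal(mom@first[1, 1], 0.70711, tolerance = 1e-5)

  # weights concentrated on one sample reproduce that sample's basis values
  D2 <- randomObservationSet(20, 3, 3, seed = 5)
  b3 <- chebyshevBasis(3)
  w <- rep(0, 20); w[7] <- 1
  m2 <- empiricalMoments(D2, b3, weights = w)
  s7 <- stateMatrix(D2)[7, ]
  expect_equal(m2@first, t(basisValues(b3)[2:3, s7 + 1]), tolerance = 1e-14)
  expect_error(empiricalMoments(D2, b3, weights = rep(0, 20)), "all zero")
  expect_error(empiricalMoments(D2, b3, weights = rep(1, 3)), "one entry per")
})

test_that("uniform data yield vanishing first moments", {
  D <- randomObservationSet(20000, 4, 3, seed = 1)
  mom <- empiricalMoments(D, chebyshevBasis(3))
  # each first moment is a mean of bounded iid values with sd <= 1/sqrt(M)
  expect_true(all(abs(mom@first) < 3 / sqrt(20000)))
})

test_that("generative weights match the two-sample closed form and normalize", {
  al <- matrix(c(0, 2, 2, 0), 2, 2)
  S <- rbind(c(1L, 1L), c(1L, 0L))
  D <- new("ObservationSet", states = S, Q = 2L, provenance = "pair")
  w <- generativeWeights(D, al)
  expect_equal(sum(w), 1, tolerance = 1e-14)
  expect_equal(w[1], exp(2) / (exp(2) + 1), tolerance = 1e-12)
  expect_equal(w[1], 0.88080, tolerance = 1e-5)
  # zero alpha: uniform
  w0 <- generativeWeights(D, matrix(0, 2, 2))
  expect_equal(w0, c(0.5, 0.5))
})

test_that("moment expansion of a histogram is the histogram", {
  for (Q in 2:6) {
    D <- randomObservationSet(200, 5, Q, seed = 100 + Q)
    b <- chebyshevBasis(Q)
    mt <- marginalTables(empiricalMoments(D, b), b, smoothing = 0)
    for (i in c(1, 4))
      expect_lt(max(abs(mt@single[i, ] - empiricalSingleTable(D, i))), 1e-10)
    for (pr in list(c(1, 2), c(2, 5)))
      expect_lt(max(abs(pairMarginal(mt, pr[1], pr[2]) -
                        empiricalPairTable(D, pr[1], pr[2]))), 1e-10)
    expect_lt(max(abs(rowSums(mt@pair) - 1)), 1e-12)
  }
})

test_that("constant observations give point-mass marginals at zero smoothing", {
  S <- matrix(1L, 30, 2)
  D <- new("ObservationSet", states = S, Q = 2L, provenance = "const")
  b <- chebyshevBasis(2)
  mt <- marginalTables(empiricalMoments(D, b), b, smoothing = 0)
  expect_equal(mt@single[1, ], c(0, 1), tolerance = 1e-12)
})

test_that("pair tables renormalize after smoothing and transpose correctly", {
  D <- randomObservationSet(40, 3, 3, seed = 2)
  b <- chebyshevBasis(3)
  mt <- marginalTables(empiricalMoments(D, b), b, smoothing = 1e-4)
  expect_lt(max(abs(rowSums(mt@pair) - 1)), 1e-12)
  expect_gte(min(mt@pair), 1e-4 / 2)  # floor survives renormalization
  expect_equal(pairMarginal(mt, 3, 1), t(pairMarginal(mt, 1, 3)))
})

test_that("uniform pair tables invert to zero couplings", {
  b <- chebyshevBasis(3)
  N <- 2
  mt <- new("MarginalTables", single = matrix(1 / 3, N, 3),
            pair = matrix(1 / 9, 1, 9), pairs = rbind(c(1L, 2L)),
            Q = 3L, smoothing = 0)
  cs <- invertCouplings(mt, b)
  expect_lt(max(abs(cs@blocks)), 1e-12)
})

test_that("exact marginals invert back to the generating block", {
  # the algebraic identity: project the exact log pair table back onto the
  # basis; checked against the independent enumeration oracle
  withr::with_seed(31, {
    for (Q in c(2, 3, 5)) {
      for (rep in 1:3) {
        blk <- matrix(0, Q, Q)
        blk[2:Q, 2:Q] <- rnorm((Q - 1)^2)
        tab <- twoNodeOracleTable(blk, Q)
        mt <- new("MarginalTables",
                  single = matrix(rep(rowSums(tab), 2), 2, Q, byrow = TRUE),
                  pair = matrix(as.vector(tab), 1, Q^2),
                  pairs = rbind(c(1L, 2L)), Q = as.integer(Q), smoothing = 0)
        cs <- invertCouplings(mt, chebyshevBasis(Q))
        rec <- couplingBlock(cs, 1, 2)
        expect_lt(max(abs(rec[2:Q, 2:Q] - blk[2:Q, 2:Q])), 1e-10)
      }
    }
  })
})

test_that("inactive-state exclusion reduces the Q=2 sums to the active term", {
  # with x=0 excluded at Q=2 only the (1,1) state contributes:
  # J^(k,l) = -Phi_k(1) Phi_l(1) log P(1,1)
  b <- chebyshevBasis(2)
  tab <- matrix(c(0.4, 0.2, 0.1, 0.3), 2, 2)
  mt <- new("MarginalTables", single = matrix(0.5, 2, 2),
            pair = matrix(as.vector(tab), 1, 4), pairs = rbind(c(1L, 2L)),
            Q = 2L, smoothing = 0)
  cs <- invertCouplings(mt, b, excludeInactive = TRUE)
  phi <- basisValues(b)[, 2]   # Phi_k(1)
  expected <- -outer(phi, phi) * log(tab[2, 2])
  expected[1, 1] <- 0
  expect_equal(couplingBlock(cs, 1, 2), expected, tolerance = 1e-12)
})

test_that("inversion refuses nonpositive marginal entries, naming the pair", {
  b <- chebyshevBasis(2)
  mt <- new("MarginalTables", single = matrix(0.5, 2, 2),
            pair = matrix(c(0, 0.5, 0.25, 0.25), 1, 4),
            pairs = rbind(c(1L, 2L)), Q = 2L, smoothing = 0)
  expect_error(invertCouplings(mt, b), "pair \\(1,2\\).*smoothing")
})

test_that("edge intensities are gauge-clean, min-max normalized and scale invariant", {
  Q <- 3L
  pairs <- canonicalPairsForTest(4)
  zero <- matrix(0, nrow(pairs), Q^2)
  csZero <- new("CouplingSet", blocks = zero, pairs = pairs, Q = Q,
                excludeInactive = FALSE)
  netZero <- edgeIntensities(csZero)
  expect_true(all(intensityMatrix(netZero) == 0))

  one <- zero
  blk <- matrix(0, Q, Q); blk[2, 3] <- 2; blk[3, 2] <- -1
  one[2, ] <- as.vector(blk)
  # field/constant entries must not contribute to the score
  one[, 1] <- 5; one[, 2] <- -3
  cs1 <- new("CouplingSet", blocks = one, pairs = pairs, Q = Q,
             excludeInactive = FALSE)
  net1 <- edgeIntensities(cs1)
  H <- intensityMatrix(net1)
  expect_equal(H[pairs[2, 1], pairs[2, 2]], 1)
  expect_equal(sum(H > 0), 2)  # the one pair, symmetric
  expect_equal(net1@rawIntensity[pairs[2, 1], pairs[2, 2]], sqrt(4 + 1))

  cs2 <- new("CouplingSet", blocks = one * 2, pairs = pairs, Q = Q,
             excludeInactive = FALSE)
  expect_equal(intensityMatrix(edgeIntensities(cs2)), H)
})

test_that("thresholding is strict and monotone", {
  withr::with_seed(6, {
    pairs <- canonicalPairsForTest(5)
    blocks <- matrix(rnorm(nrow(pairs) * 4), nrow(pairs), 4)
    blocks[, 1] <- 0
    cs <- new("CouplingSet", blocks = blocks, pairs = pairs, Q = 2L,
              excludeInactive = FALSE)
  })
  net <- edgeIntensities(cs)
  expect_identical(sum(adjacencyMatrix(thresholdNetwork(net, 1))), 0L)
  n0 <- thresholdNetwork(net, 0)
  expect_equal(sum(adjacencyMatrix(n0)) / 2, sum(intensityMatrix(net)[upper.tri(diag(5))] > 0))
  links <- vapply(seq(0, 1, 0.1), function(tm)
    sum(adjacencyMatrix(thresholdNetwork(net, tm))), 0L)
  expect_true(all(diff(links) <= 0))
  expect_error(thresholdNetwork(net, 1.5), "\\[0, 1\\]")
})

test_that("indirect couplings score below direct ones on a chain", {
  # 3-node chain with moderate coupling: the non-adjacent pair's inverted
  # intensity must be strictly smaller than either adjacent pair's
  J <- matrix(0, 2, 2); J[2, 2] <- -1
  m <- pottsModel(3, 2, rbind(c(1, 2), c(2, 3)), list(J, J))
  d <- exactDistribution(m)
  pairs <- canonicalPairsForTest(3)
  pairRows <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r)
    as.vector(d$pairTable(pairs[r, 1], pairs[r, 2]))))
  mt <- new("MarginalTables", single = d$single, pair = pairRows,
            pairs = pairs, Q = 2L, smoothing = 0)
  cs <- invertCouplings(mt, chebyshevBasis(2))
  net <- edgeIntensities(cs)
  raw <- net@rawIntensity
  expect_lt(raw[1, 3], raw[1, 2])
  expect_lt(raw[1, 3], raw[2, 3])
})

test_that("Gibbs-estimated couplings tighten with sample size", {
  blk <- matrix(0, 2, 2); blk[2, 2] <- -1.2
  m <- pottsModel(2, 2, rbind(c(1, 2)), list(blk))
  b <- chebyshevBasis(2)
  rmse <- function(n, seeds) sqrt(mean(vapply(seeds, function(s) {
    D <- gibbsSample(m, samplerConfig(nSamples = n, burnIn = 200, thin = 1,
                                      seed = s))
    mt <- marginalTables(empiricalMoments(D, b), b, smoothing = 1e-9)
    (couplingBlock(invertCouplings(mt, b), 1, 2)[2, 2] - blk[2, 2])^2
  }, 0)))
  # quadrupling the samples should halve the rmse; 12 independent chains
  # per size, with slack for replicate noise
  expect_lt(rmse(40000L, 201:212), 0.85 * rmse(10000L, 101:112))
})
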