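test_that("sampler config validates its fields", {
  cfg <- samplerConfig()
  expect_identical(cfg$nSamples, 100000L)
  expect_identical(cfg$burnIn, 1000L)
  expect_identical(cfg$thin, 5L)
  expect_error(samplerConfig(nSamples = 0), "nSamples")
  expect_error(samplerConfig(burnIn = -1), "burnIn")
  expect_error(samplerConfig(thin = 0), "thin")
})

test_that("identical seeds give identical samples; different seeds differ", {
  m <- fixturePreset("chain3")$model
  cfg <- samplerConfig(nSamples = 500, burnIn = 50, thin = 2, seed = 11)
  D1 <- gibbsSample(m, cfg)
  D2 <- gibbsSample(m, cfg)
  expect_identical(stateMatrix(D1), stateMatrix(D2))
  D3 <- gibbsSample(m, samplerConfig(nSamples = 500, burnIn = 50, thin = 2,
                                     seed = 12))
  expect_false(identical(stateMatrix(D1), stateMatrix(D3)))
})

test_that("zero-coupling models sample uniformly", {
  m <- pottsModel(4, 3)
  D <- gibbsSample(m, samplerConfig(nSamples = 10000, burnIn = 10, thin = 1,
                                    seed = 5))
  n <- 4 * 10000
  freq <- tabulate(stateMatrix(D) + 1L, 3) / n
  sigma <- sqrt((1 / 3) * (2 / 3) / n)
  expect_true(all(abs(freq - 1 / 3) < 3 * sigma))
})

test_that("Gibbs pair tables converge to the exact distribution on a ferromagnetic chain", {
  m <- fixturePreset("chain3")$model
  d <- exactDistribution(m)
  D <- gibbsSample(m, samplerConfig(nSamples = 50000, burnIn = 1000,
                                    thin = 5, seed = 3))
  for (pr in list(c(1, 2), c(2, 3), c(1, 3))) {
    emp <- empiricalPairTable(D, pr[1], pr[2])
    tv <- 0.5 * sum(abs(emp - d$pairTable(pr[1], pr[2])))
    expect_lt(tv, 0.02)
  }
})

test_that("alpha sampler matches the two-node closed form and is monotone in alpha", {
  closedForm <- function(a) exp(a) / (exp(a) + 1)  # P(x1 == x2), Q = 2
  rates <- vapply(c(0.5, 2, 4), function(a) {
    al <- matrix(c(0, a, a, 0), 2, 2)
    D <- sampleFromAlpha(al, 2, samplerConfig(nSamples = 50000, burnIn = 200,
                                              thin = 1, seed = 21))
    mean(stateMatrix(D)[, 1] == stateMatrix(D)[, 2])
  }, 0)
  p <- closedForm(2)
  expect_equal(p, 0.88080, tolerance = 1e-4)
  sigma <- sqrt(p * (1 - p) / 50000)
  expect_lt(abs(rates[2] - p), 3 * sigma)
  expect_true(all(diff(rates) > 0))
})

test_that("alpha sampler handles zero alpha and rejects asymmetry", {
  D <- sampleFromAlpha(matrix(0, 3, 3), 4,
                       samplerConfig(nSamples = 8000, burnIn = 0, thin = 1,
                                     seed = 2))
  freq <- tabulate(stateMatrix(D) + 1L, 4) / (3 * 8000)
  sigma <- sqrt(0.25 * 0.75 / (3 * 8000))
  expect_true(all(abs(freq - 0.25) < 3 * sigma))
  bad <- matrix(c(0, 1, 0, 0), 2, 2)
  expect_error(sampleFromAlpha(bad, 2), "symmetric")
})

test_that("long-run Gibbs distribution matches exact enumeration on a loopy model", {
  # triangle with mixed couplings: exercises a graph with a cycle
  withr::with_seed(8, {
    blks <- lapply(1:3, function(i) {
      b <- matrix(0, 3, 3); b[2:3, 2:3] <- rnorm(4, sd = 0.7); b
    })
  })
  m <- pottsModel(3, 3, rbind(c(1, 2), c(1, 3), c(2, 3)), blks)
  d <- exactDistribution(m)
  D <- gibbsSample(m, samplerConfig(nSamples = 50000, burnIn = 1000,
                                    thin = 5, seed = 17))
  S <- stateMatrix(D)
  key <- S[, 1] * 9 + S[, 2] * 3 + S[, 3]
  emp <- tabulate(key + 1L, 27) / nrow(S)
  exKey <- d$configs[, 1] * 9 + d$configs[, 2] * 3 + d$configs[, 3]
  tv <- 0.5 * sum(abs(emp - d$prob[order(exKey)]))
  expect_lt(tv, 0.02)
})

test_that("observation TSV round-trips through files", {
  D <- gibbsSample(fixturePreset("chain3")$model,
                   samplerConfig(nSamples = 100, burnIn = 10, thin = 1,
                                 seed = 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeObservations(D, path, seed = 1)
  D2 <- readObservations(path)
  expect_identical(stateMatrix(D2), stateMatrix(D))
  expect_identical(nStates(D2), nStates(D))
})
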