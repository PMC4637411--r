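test_that("state assignment encodes activity exactly at Q = 2", {
  aff <- affFromActivities(list(c(1, 2), c(1, 2, 3), 2), N = 4)
  D <- assignStates(aff, 2, seed = 1)
  expect_equal(stateMatrix(D), t(affiliationEntries(aff)), ignore_attr = TRUE)
})

test_that("inactive states at Q > 2 are uniform over the non-active states", {
  aff <- affFromActivities(replicate(400, c(1, 2), simplify = FALSE), N = 27)
  D <- assignStates(aff, 5, seed = 7)
  S <- stateMatrix(D)
  # active entries untouched
  expect_true(all(S[, 1:2] == 1L))
  inact <- S[, 3:27]
  expect_true(all(inact %in% c(0L, 2L, 3L, 4L)))
  n <- length(inact)
  freq <- tabulate(match(inact, c(0L, 2L, 3L, 4L)), 4) / n
  sigma <- sqrt(0.25 * 0.75 / n)
  expect_true(all(abs(freq - 0.25) < 3 * sigma))
  # determinism and active-set preservation
  expect_identical(S, stateMatrix(assignStates(aff, 5, seed = 7)))
  expect_identical(which(S == 1L), which(t(affiliationEntries(aff)) == 1))
  expect_error(assignStates(aff, 1), "Q must be")
})

test_that("alpha weighting schemes match hand-computed examples", {
  # bills {1,2} then {1,2,3} over 3 members
  aff <- affFromActivities(list(c(1, 2), c(1, 2, 3)), N = 3)
  expect_equal(alphaEntries(alphaLiu(aff))[1, 2], 1 / 2 + 1 / 3,
               tolerance = 1e-12)
  expect_equal(alphaEntries(alphaLiu(aff))[1, 2], 0.83333, tolerance = 1e-5)

  # bills {1,2} (n=2) and {1} (n=1) over 2 members
  aff2 <- affFromActivities(list(c(1, 2), 1), N = 2)
  expect_equal(alphaEntries(alphaFrequentist(aff2))[1, 2], 0.25,
               tolerance = 1e-12)
  expect_equal(alphaEntries(alphaFrequentist(aff2)),
               alphaEntries(alphaLiu(aff2)) / 2)
  expect_equal(alphaEntries(alphaActivityAdjusted(aff2))[1, 2], 1 / 6,
               tolerance = 1e-12)

  # never co-active pairs and fully inactive members get zero
  aff3 <- affFromActivities(list(1, 2), N = 4)
  expect_true(all(alphaEntries(alphaLiu(aff3))[1, 2:4] == 0))
  expect_true(all(alphaEntries(alphaActivityAdjusted(aff3))[4, ] == 0))
})

test_that("all alpha schemes produce symmetric nonnegative zero-diagonal matrices", {
  withr::with_seed(13, {
    for (rep in 1:5) {
      A <- matrix(rbinom(20 * 40, 1, 0.2), 20, 40)
      A[, colSums(A) == 0][1, ] <- 1   # avoid empty-activity warnings
      aff <- affiliationMatrix(A)
      for (f in list(alphaLiu, alphaFrequentist, alphaActivityAdjusted)) {
        a <- alphaEntries(f(aff))
        expect_lt(max(abs(a - t(a))), 1e-14)
        expect_gte(min(a), 0)
        expect_true(all(diag(a) == 0))
      }
    }
  })
})

test_that("empty activities are skipped with a warning", {
  A <- matrix(0, 3, 2); A[1:2, 1] <- 1
  expect_warning(aff <- affiliationMatrix(A), "no participants")
  expect_equal(alphaEntries(alphaLiu(aff))[1, 2], 0.5)
})

test_that("minimal Q honors the inactive-match inequality", {
  expect_identical(minQForInactive(338, 8, 0.024), 40L)
  expect_identical(minQForInactive(10, 5, 1), 2L)
  expect_identical(minQForInactive(10, 10, 0.3), 2L)
  expect_error(minQForInactive(10, 5, 0), "positive")
  expect_error(minQForInactive(10, 12), "nActive")
  # non-increasing in pAct and in nActive
  qs <- vapply(c(0.01, 0.02, 0.05, 0.2, 1), function(p)
    minQForInactive(338, 8, p), 0L)
  expect_true(all(diff(qs) <= 0))
  qa <- vapply(c(0, 4, 8, 100, 338), function(na)
    minQForInactive(338, na, 0.024), 0L)
  expect_true(all(diff(qa) <= 0))
  # returned Q satisfies the inequality, Q-1 does not (when Q > 2)
  for (p in c(0.01, 0.024, 0.1)) {
    q <- minQForInactive(338, 8, p)
    pIna <- function(Q) (338 - 8) / ((Q + 1) * 338)
    expect_lte(pIna(q), p)
    if (q > 2) expect_gt(pIna(q - 1), p)
  }
})
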