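#' Construct an affiliation matrix
#'
#' @param entries N x M binary matrix, members in rows, activities in
#'   columns.
#' @param memberIds,activityIds optional id vectors; defaults are
#'   \code{m1..mN} / \code{a1..aM} or existing dimnames.
#' @return an [AffiliationMatrix]. Warns when an activity column has no
#'   participants (such columns are skipped by the alpha weightings).
#' @export
affiliationMatrix <- function(entries, memberIds = NULL, activityIds = NULL) {
  entries <- as.matrix(entries)
  if (is.null(memberIds))
    memberIds <- rownames(entries) %||% paste0("m", seq_len(nrow(entries)))
  if (is.null(activityIds))
    activityIds <- colnames(entries) %||% paste0("a", seq_len(ncol(entries)))
  dimnames(entries) <- NULL
  storage.mode(entries) <- "double"
  if (ncol(entries) && any(colSums(entries) == 0))
    warning(sum(colSums(entries) == 0), " activity column(s) have no ",
            "participants; they will be skipped by the alpha weightings")
  new("AffiliationMatrix", entries = entries,
      memberIds = as.character(memberIds),
      activityIds = as.character(activityIds))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
setMethod("affiliationEntries", "AffiliationMatrix", function(x) x@entries)
#' @export
setMethod("nNodes", "AffiliationMatrix", function(x) nrow(x@entries))

#' Number of activities
#' @param x an [AffiliationMatrix].
#' @return integer.
#' @export
nActivities <- function(x) {
  stopifnot(is(x, "AffiliationMatrix"))
  ncol(x@entries)
}

setMethod("show", "AffiliationMatrix", function(object) {
  cat("AffiliationMatrix:", nrow(object@entries), "members x",
      ncol(object@entries), "activities, fill =",
      signif(mean(object@entries), 3), "\n")
})

#' @export
setMethod("alphaEntries", "AlphaMatrix", function(x) x@entries)

setMethod("show", "AlphaMatrix", function(object) {
  off <- object@entries[upper.tri(object@entries)]
  cat("AlphaMatrix (", object@scheme, "): ", nrow(object@entries), " nodes, ",
      "mean off-diagonal = ", signif(mean(off), 5), "\n", sep = "")
})

#' Turn an affiliation matrix into Potts observations
#'
#' Each activity becomes one observation (a "snapshot" of the N nodes).
#' Active members (entry 1) get the active state 1. Inactive members get
#' state 0 when \code{Q = 2}; for \code{Q > 2} each inactive entry draws one
#' of the Q-1 non-active states \{0, 2, 3, ..., Q-1\} uniformly and
#' independently, so that spurious correlations among co-inactive members
#' are diluted across states instead of piling onto a single passive state.
#' The draw is seeded and does not disturb the caller's RNG state.
#'
#' @param aff an [AffiliationMatrix].
#' @param Q integer state count >= 2.
#' @param seed integer seed for the inactive-state draws.
#' @return an [ObservationSet] with one row per activity.
#' @export
assignStates <- function(aff, Q, seed = 1L) {
  stopifnot(is(aff, "AffiliationMatrix"))
  if (!is.numeric(Q) || length(Q) != 1L || Q != round(Q) || Q < 2)
    stop("Q must be a single integer >= 2")
  Q <- as.integer(Q)
  A <- t(aff@entries)                      # M x N, one row per activity
  states <- matrix(0L, nrow(A), ncol(A))
  states[A == 1] <- 1L
  if (Q > 2L) {
    idx <- which(A == 0)
    draws <- withSeed(seed,
      sample(0:(Q - 2L), length(idx), replace = TRUE))
    draws[draws >= 1L] <- draws[draws >= 1L] + 1L   # {0,1,..,Q-2} -> {0,2,..,Q-1}
    states[idx] <- draws
  }
  new("ObservationSet", states = states, Q = Q,
      provenance = sprintf("assigned(Q=%d,seed=%d)", Q, as.integer(seed)))
}

# Co-active counts weighted by 1/n_mu: sum_mu delta(d_i, d_j, 1)/n_mu.
# Zero-participant activities are skipped (the constructor already warned).
weightedCoactive <- function(aff) {
  A <- aff@entries
  n_mu <- colSums(A)
  keep <- n_mu > 0
  W <- A[, keep, drop = FALSE] %*%
    (t(A[, keep, drop = FALSE]) / n_mu[keep])
  diag(W) <- 0
  W
}

#' Liu-style weighted co-occurrence counts (unnormalized)
#'
#' \eqn{\alpha_{ij} = \sum_\mu \delta(d_i^\mu, d_j^\mu, 1)/n_\mu}: each
#' activity in which both members were active contributes the reciprocal of
#' its participant count \eqn{n_\mu}. \eqn{\delta(i,j,k)} is the generalized
#' Kronecker delta, 1 iff \eqn{i = j = k}.
#'
#' @param aff an [AffiliationMatrix].
#' @return an [AlphaMatrix] with scheme \code{"liu"}.
#' @export
alphaLiu <- function(aff) {
  stopifnot(is(aff, "AffiliationMatrix"))
  new("AlphaMatrix", entries = weightedCoactive(aff), scheme = "liu")
}

#' Frequentist co-activity probability
#'
#' \eqn{\alpha_{ij} = \frac{1}{M}\sum_\mu \delta(d_i^\mu, d_j^\mu, 1)/n_\mu}
#' — the per-activity average of the weighted co-occurrence count. Penalizes
#' pairs with low participation rates.
#'
#' @param aff an [AffiliationMatrix].
#' @return an [AlphaMatrix] with scheme \code{"frequentist"}.
#' @export
alphaFrequentist <- function(aff) {
  stopifnot(is(aff, "AffiliationMatrix"))
  M <- ncol(aff@entries)
  if (M < 1L) stop("affiliation must have at least one activity")
  new("AlphaMatrix", entries = weightedCoactive(aff) / M,
      scheme = "frequentist")
}

#' Activity-adjusted co-activity weighting
#'
#' \deqn{\alpha_{ij} = \frac{\sum_\mu \delta(d_i^\mu, d_j^\mu, 1)/n_\mu}
#'   {\sum_\mu [\delta(d_i^\mu, 1) + \delta(d_j^\mu, 1)]}}
#' The denominator is the pair's combined activity count, which removes the
#' frequentist scheme's bias toward highly active members. Pairs whose
#' denominator is zero (both members inactive everywhere) get 0.
#'
#' @param aff an [AffiliationMatrix].
#' @return an [AlphaMatrix] with scheme \code{"activity_adjusted"}.
#' @export
alphaActivityAdjusted <- function(aff) {
  stopifnot(is(aff, "AffiliationMatrix"))
  num <- weightedCoactive(aff)
  act <- rowSums(aff@entries)
  den <- outer(act, act, "+")
  a <- ifelse(den > 0, num / den, 0)
  diag(a) <- 0
  new("AlphaMatrix", entries = a, scheme = "activity_adjusted")
}

#' Constant alpha matrix
#'
#' All off-diagonal entries equal to \code{value}; the numerical-convergence
#' fallback recorded for the pure observational strategy.
#'
#' @param N node count.
#' @param value constant entry (default 0.01).
#' @return an [AlphaMatrix] with scheme \code{"constant:<value>"}.
#' @export
alphaConstant <- function(N, value = 0.01) {
  a <- matrix(value, N, N)
  diag(a) <- 0
  new("AlphaMatrix", entries = a, scheme = paste0("constant:", value))
}

#' Average empirical probability of sharing the active state
#'
#' \eqn{p_{act} = N_A / N}, with \eqn{N_A} the mean number of active members
#' per activity. This is the quantity the minimal-Q inequality compares
#' against.
#'
#' @param N member count.
#' @param nActive mean active members per activity (\eqn{N_A}).
#' @return numeric probability.
#' @export
activeMatchProbability <- function(N, nActive) {
  if (N <= 0) stop("N must be positive")
  nActive / N
}

#' Smallest Q keeping random inactive matches below active matches
#'
#' Returns the smallest integer \eqn{Q \ge 2} for which the random
#' probability of assigning two nodes the same inactive state,
#' \eqn{p_{ina} = (N - N_A) / ((Q + 1) N)}, does not exceed the active-state
#' match probability \eqn{p_{act}}. The \eqn{p_{ina}} formula is used
#' verbatim as the model's calibration rule (see the methods vignette for a
#' note on its relation to the uniform assignment actually performed by
#' [assignStates()]).
#'
#' @param N member count.
#' @param nActive mean active members per activity (\eqn{N_A}),
#'   \eqn{0 \le N_A \le N}.
#' @param pAct active match probability in (0, 1]; defaults to
#'   [activeMatchProbability()] of the same arguments.
#' @return integer Q >= 2.
#' @examples
#' minQForInactive(338, 8, 0.024)  # 40
#' @export
minQForInactive <- function(N, nActive, pAct = activeMatchProbability(N, nActive)) {
  if (nActive < 0 || nActive > N) stop("nActive must lie in [0, N]")
  if (!is.numeric(pAct) || pAct <= 0) stop("pAct must be positive")
  if (pAct > 1) stop("pAct must be <= 1")
  pIna <- function(Q) (N - nActive) / ((Q + 1) * N)
  Q <- max(2L, as.integer(ceiling((N - nActive) / (N * pAct) - 1 - 1e-9)))
  while (pIna(Q) > pAct) Q <- Q + 1L   # guard against rounding at the boundary
  while (Q > 2L && pIna(Q - 1L) <= pAct) Q <- Q - 1L
  Q
}
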