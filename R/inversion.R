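#' Sample moments of the basis polynomials
#'
#' Computes the first moments \eqn{\langle\Phi_k(x_i)\rangle_D} (k >= 1) and
#' all pairwise second moments \eqn{\langle\Phi_k(x_i)\Phi_l(x_j)\rangle_D},
#' either as plain sample averages (uniform weights 1/M) or as weighted
#' averages \eqn{\sum_\mu w_\mu f(d^\mu)} with supplied nonnegative weights —
#' the reweighting mechanism of the semi-observational strategy, where the
#' weights come from the alpha-parameterized generative model via
#' [generativeWeights()].
#'
#' @param D an [ObservationSet].
#' @param basis a [ChebyshevBasis] with Q matching \code{D}.
#' @param weights optional numeric vector of per-sample weights (length M,
#'   nonnegative, not all zero); normalized internally to sum 1.
#' @return a [MomentSet].
#' @export
empiricalMoments <- function(D, basis, weights = NULL) {
  stopifnot(is(D, "ObservationSet"), is(basis, "ChebyshevBasis"))
  if (basis@Q != D@Q) stop("basis Q must match observation Q")
  S <- D@states
  M <- nrow(S); N <- ncol(S); Q <- D@Q
  if (is.null(weights)) {
    w <- rep(1 / M, M)
    weighting <- "uniform"
  } else {
    if (length(weights) != M) stop("weights must have one entry per sample")
    if (any(weights < 0) || !all(is.finite(weights)))
      stop("weights must be finite and nonnegative")
    if (sum(weights) == 0) stop("weights must not be all zero")
    w <- weights / sum(weights)
    weighting <- "weighted"
  }
  Phi <- basis@values
  # B[[k]] = Phi_k applied entrywise to the sample matrix (M x N)
  B <- lapply(seq_len(Q - 1L), function(k) {
    matrix(Phi[k + 1L, S + 1L], M, N)
  })
  first <- vapply(B, function(Bk) colSums(w * Bk), numeric(N))
  first <- matrix(first, N, Q - 1L)
  pairs <- canonicalPairs(N)
  iu <- cbind(pairs[, 1], pairs[, 2])
  second <- matrix(0, nrow(pairs), (Q - 1L)^2)
  for (l in seq_len(Q - 1L)) {
    Bl <- B[[l]]
    for (k in seq_len(Q - 1L)) {
      Ckl <- crossprod(B[[k]] * w, Bl)    # N x N weighted cross-moments
      second[, k + (Q - 1L) * (l - 1L)] <- Ckl[iu]
    }
  }
  new("MomentSet", first = first, second = second, pairs = pairs,
      Q = as.integer(Q), weighting = weighting)
}

#' Per-sample weights from the alpha generative model
#'
#' Weights each observed sample by its probability under the
#' alpha-parameterized Potts model:
#' \eqn{w_\mu \propto \exp[\tfrac{1}{2}\sum_{i \ne j} \alpha_{ij}
#' \delta(d_i^\mu, d_j^\mu)]}. Log-weights are shifted by their maximum
#' before exponentiation (no overflow possible) and normalized to sum 1.
#'
#' @param D an [ObservationSet].
#' @param alpha an [AlphaMatrix] (or symmetric matrix) over the same nodes.
#' @return numeric vector of M normalized weights.
#' @export
generativeWeights <- function(D, alpha) {
  stopifnot(is(D, "ObservationSet"))
  a <- if (is(alpha, "AlphaMatrix")) alpha@entries else as.matrix(alpha)
  S <- D@states
  if (nrow(a) != ncol(S)) stop("alpha dimension must match node count")
  logw <- numeric(nrow(S))
  for (s in 0:(D@Q - 1L)) {
    U <- (S == s) * 1                     # M x N indicator of state s
    logw <- logw + rowSums((U %*% a) * U)
  }
  logw <- logw / 2
  w <- exp(logw - max(logw))
  w / sum(w)
}

# Kernel matrices reused by the expansion and the inversion.
# pairKernel: (Q-1)^2 x Q^2, rows (k,l) k-fastest, cols (x,y) x-fastest.
pairKernel <- function(basis) {
  P1 <- basis@values[-1L, , drop = FALSE]
  kronecker(P1, P1)
}

#' Marginal tables from moments
#'
#' Expands the single-site and pairwise marginal probability tables from a
#' [MomentSet]:
#' \deqn{P_i(x) = 1/Q + \sum_{k\ge 1} \langle\Phi_k(x_i)\rangle \Phi_k(x)}
#' \deqn{P_{(i,j)}(x,y) = 1/Q^2 + \frac{1}{Q}\sum_{k\ge 1}
#'   [\langle\Phi_k(x_i)\rangle\Phi_k(x) +
#'    \langle\Phi_k(x_j)\rangle\Phi_k(y)] + \sum_{k,l\ge 1}
#'   \langle\Phi_k\Phi_l\rangle \Phi_k(x)\Phi_l(y)}
#' then clips every entry below at \code{smoothing} and renormalizes each
#' table to sum 1. With uniform weights and zero smoothing the tables equal
#' the empirical frequency tables of the observations exactly (the
#' orthonormal expansion of a histogram is the histogram); smoothing > 0 is
#' needed before inversion whenever a table contains zeros.
#'
#' @param m a [MomentSet].
#' @param basis a [ChebyshevBasis] with matching Q.
#' @param smoothing nonnegative floor; \code{1e-6} by default.
#'   \code{1/(Q^2 M)} is a natural sample-size-scaled alternative.
#' @return a [MarginalTables].
#' @export
marginalTables <- function(m, basis, smoothing = 1e-6) {
  stopifnot(is(m, "MomentSet"), is(basis, "ChebyshevBasis"))
  if (basis@Q != m@Q) stop("basis Q must match moment Q")
  if (smoothing < 0) stop("smoothing must be >= 0")
  Q <- m@Q
  P1 <- basis@values[-1L, , drop = FALSE]       # (Q-1) x Q
  single <- 1 / Q + m@first %*% P1              # N x Q
  F1 <- m@first %*% P1                          # node-wise field terms
  i <- m@pairs[, 1]; j <- m@pairs[, 2]
  xIdx <- rep(seq_len(Q), times = Q)            # x fastest in (x,y)
  yIdx <- rep(seq_len(Q), each = Q)
  pair <- 1 / Q^2 +
    (F1[i, xIdx, drop = FALSE] + F1[j, yIdx, drop = FALSE]) / Q +
    m@second %*% pairKernel(basis)
  clipRenorm <- function(P) {
    P <- pmax(P, smoothing)
    P / rowSums(P)
  }
  new("MarginalTables", single = clipRenorm(single),
      pair = clipRenorm(pair), pairs = m@pairs, Q = as.integer(Q),
      smoothing = smoothing)
}

#' Extract one pairwise marginal table
#'
#' @param mt a [MarginalTables].
#' @param i,j node indices (1-based, any order).
#' @return Q x Q matrix, rows = states of the lower-indexed node.
#' @export
pairMarginal <- function(mt, i, j) {
  stopifnot(is(mt, "MarginalTables"))
  lo <- min(i, j); hi <- max(i, j)
  N <- nrow(mt@single)
  tab <- matrix(mt@pair[pairRow(N, lo, hi), ], mt@Q, mt@Q)
  if (i <= j) tab else t(tab)
}

#' Invert pairwise marginals into coupling blocks
#'
#' The closed-form Bethe/moment-matching inversion
#' \deqn{J_{(i,j)}^{(k,l)} = -\sum_{x_i}\sum_{x_j} \Phi_k(x_i) \Phi_l(x_j)
#'   \ln P_{(i,j)}(x_i, x_j)}
#' computed for all \eqn{(k,l) \ne (0,0)}. The state sums run over
#' \eqn{\{0..Q-1\}}, or over \eqn{\{1..Q-1\}} when \code{excludeInactive}
#' is set — the variant that drops correlations carried by the inactive
#' state 0, required by the pure observational strategy at Q = 2.
#'
#' @param mt a [MarginalTables] (all pair entries must be strictly
#'   positive; raise the smoothing otherwise).
#' @param basis a [ChebyshevBasis] with matching Q.
#' @param excludeInactive logical; exclude state 0 from the sums.
#' @return a [CouplingSet].
#' @export
invertCouplings <- function(mt, basis, excludeInactive = FALSE) {
  stopifnot(is(mt, "MarginalTables"), is(basis, "ChebyshevBasis"))
  if (basis@Q != mt@Q) stop("basis Q must match marginal Q")
  Q <- mt@Q
  keepState <- if (excludeInactive) 2:Q else 1:Q
  usedCols <- which(rep(seq_len(Q), times = Q) %in% keepState &
                    rep(seq_len(Q), each = Q) %in% keepState)
  bad <- which(apply(mt@pair[, usedCols, drop = FALSE] <= 0, 1L, any))
  if (length(bad)) {
    p <- mt@pairs[bad[1], ]
    stop("pair (", p[1], ",", p[2], ") has a nonpositive marginal entry; ",
         "increase the smoothing before inverting")
  }
  PhiS <- basis@values
  if (excludeInactive) PhiS[, 1L] <- 0     # drop x = 0 from the sums
  Kfull <- kronecker(PhiS, PhiS)           # Q^2 x Q^2, (k,l) x (x,y)
  L <- log(mt@pair)
  blocks <- -tcrossprod(L, Kfull)          # npairs x Q^2, (k,l) k-fastest
  blocks[, 1L] <- 0                        # (0,0) absorbed constant
  new("CouplingSet", blocks = blocks, pairs = mt@pairs, Q = as.integer(Q),
      excludeInactive = excludeInactive)
}

#' Extract one coupling block
#'
#' @param cs a [CouplingSet].
#' @param i,j node indices (1-based, i < j in canonical order).
#' @return Q x Q matrix, entry \code{[k+1, l+1]} = \eqn{J^{(k,l)}}.
#' @export
couplingBlock <- function(cs, i, j) {
  stopifnot(is(cs, "CouplingSet"), i < j)
  N <- max(cs@pairs)
  matrix(cs@blocks[pairRow(N, i, j), ], cs@Q, cs@Q)
}

#' Scalar edge intensities from coupling blocks
#'
#' Scores each pair by the Frobenius norm of the interaction sub-block
#' (entries with \eqn{k, l \ge 1}) of its inverted coupling — the standard
#' gauge-clean coupling-strength score of inverse-Potts contact inference
#' (field and constant terms excluded) — then min-max normalizes the scores
#' over all off-diagonal pairs into [0, 1]. If all raw scores are equal the
#' normalized intensities are all 0.
#'
#' @param cs a [CouplingSet].
#' @param memberIds optional node ids.
#' @param meta optional named list merged into the network metadata.
#' @return a [ReconstructedNetwork] (un-thresholded: \code{tm} is NA and the
#'   adjacency is empty until [thresholdNetwork()] is applied).
#' @export
edgeIntensities <- function(cs, memberIds = NULL, meta = list()) {
  stopifnot(is(cs, "CouplingSet"))
  Q <- cs@Q
  N <- max(cs@pairs)
  interact <- which(rep(seq_len(Q), times = Q) >= 2 &
                    rep(seq_len(Q), each = Q) >= 2)
  raw <- sqrt(rowSums(cs@blocks[, interact, drop = FALSE]^2))
  rng <- range(raw)
  normd <- if (rng[2] > rng[1]) (raw - rng[1]) / (rng[2] - rng[1])
           else rep(0, length(raw))
  if (is.null(memberIds)) memberIds <- paste0("m", seq_len(N))
  new("ReconstructedNetwork",
      intensity = pairsToMatrix(normd, cs@pairs, N),
      rawIntensity = pairsToMatrix(raw, cs@pairs, N),
      adjacency = matrix(FALSE, N, N), tm = NA_real_,
      memberIds = as.character(memberIds),
      meta = c(meta, list(normalization = "minmax",
                          intensity = "frobenius(k,l>=1)",
                          excludeInactive = cs@excludeInactive)))
}

#' Threshold a reconstructed network
#'
#' Links every pair whose normalized intensity strictly exceeds \code{tm}
#' (so \code{tm = 1} gives the empty graph) and records the threshold.
#'
#' @param net a [ReconstructedNetwork].
#' @param tm threshold in [0, 1].
#' @return the network with updated \code{adjacency} and \code{tm}.
#' @export
thresholdNetwork <- function(net, tm) {
  stopifnot(is(net, "ReconstructedNetwork"))
  if (!is.numeric(tm) || length(tm) != 1L || tm < 0 || tm > 1)
    stop("tm must be a single value in [0, 1]")
  adj <- net@intensity > tm
  diag(adj) <- FALSE
  initialize(net, adjacency = adj, tm = tm)
}

#' @export
setMethod("intensityMatrix", "ReconstructedNetwork", function(x) x@intensity)
#' @export
setMethod("adjacencyMatrix", "ReconstructedNetwork", function(x) x@adjacency)
#' @export
setMethod("nNodes", "ReconstructedNetwork", function(x) nrow(x@intensity))

setMethod("show", "ReconstructedNetwork", function(object) {
  N <- nrow(object@intensity)
  cat("ReconstructedNetwork:", N, "nodes")
  if (!is.na(object@tm))
    cat(",", sum(object@adjacency) / 2, "links at t_m =", object@tm)
  if (!is.null(object@meta$strategy))
    cat(" [", object@meta$strategy, "]", sep = "")
  cat("\n")
})
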