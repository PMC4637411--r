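#' Weighted Newman modularity of a partition
#'
#' \eqn{Q = \frac{1}{2m}\sum_{ij}(A_{ij} - k_i k_j / 2m)\,\delta(c_i, c_j)}
#' with strengths \eqn{k_i} and total weight \eqn{2m = \sum_{ij} A_{ij}}.
#' Returns 0 for an empty graph.
#'
#' @param weights symmetric nonnegative N x N matrix, zero diagonal.
#' @param labels integer community labels of length N.
#' @return numeric modularity.
#' @export
weightedModularity <- function(weights, labels) {
  W <- as.matrix(weights)
  two_m <- sum(W)
  if (two_m == 0) return(0)
  k <- rowSums(W)
  same <- outer(labels, labels, "==")
  sum((W - outer(k, k) / two_m)[same]) / two_m
}

# Surviving weights of a network: after thresholding, links keep their
# intensity and non-links drop to zero; before thresholding, the full
# intensity matrix.
survivingWeights <- function(net) {
  if (is(net, "ReconstructedNetwork")) {
    W <- net@intensity
    if (!is.na(net@tm)) W <- W * net@adjacency
    rownames(W) <- colnames(W) <- net@memberIds
    W
  } else as.matrix(net)
}

#' Greedy modularity (CNM) community detection with forced merging
#'
#' Clauset-Newman-Moore style agglomeration on the weighted graph: every
#' node starts in its own community and the pair of communities whose merge
#' yields the largest modularity gain is merged repeatedly, stopping at the
#' modularity maximum (no merge with positive gain remains). If
#' \code{forceK} is given, merging continues past the maximum — always
#' taking the best available gain, even when negative — until exactly
#' \code{forceK} communities remain. All ties are broken deterministically
#' by the lexicographically smallest pair of community ids (a community's id
#' is its smallest member's index).
#'
#' @param weights symmetric nonnegative N x N matrix (zero diagonal), or a
#'   [ReconstructedNetwork]; for a thresholded network the surviving links
#'   keep their weights and severed pairs count as 0.
#' @param forceK optional integer in 1..N: exact number of communities to
#'   return.
#' @return a [CommunityPartition]; labels are renumbered 1..k in order of
#'   community id and named by member id when available.
#' @export
cnmCommunities <- function(weights, forceK = NULL) {
  W <- survivingWeights(weights)
  N <- nrow(W)
  if (ncol(W) != N) stop("weights must be square")
  if (max(abs(W - t(W))) > 1e-9) stop("weights must be symmetric")
  if (min(W) < 0) stop("weights must be nonnegative")
  ids0 <- rownames(W) %||% paste0("m", seq_len(N))
  diag(W) <- 0
  if (!is.null(forceK)) {
    forceK <- as.integer(forceK)
    if (forceK < 1L || forceK > N) stop("forceK must lie in 1..N")
  }

  two_m <- sum(W)
  membership <- seq_len(N)
  if (two_m > 0) {
    E <- W                       # community-level weight matrix
    a <- rowSums(E)
    cid <- seq_len(N)            # community id = smallest member index
    repeat {
      C <- length(cid)
      stopAtMax <- is.null(forceK)
      if (!stopAtMax && C <= forceK) break
      if (C <= 1L) break
      G <- 2 * (E / two_m - outer(a, a) / two_m^2)
      G[lower.tri(G, diag = TRUE)] <- -Inf
      if (stopAtMax) G[E <= 0] <- -Inf   # classic CNM: only connected pairs
      best <- max(G)
      if (stopAtMax && best <= 0) break
      if (!is.finite(best)) {
        # forced merging of a fully disconnected remainder: zero-gain merge
        G <- matrix(0, C, C); G[lower.tri(G, diag = TRUE)] <- -Inf
        best <- 0
      }
      cand <- which(G == best, arr.ind = TRUE)
      ord <- order(cid[cand[, 1]], cid[cand[, 2]])
      c1 <- cand[ord[1], 1]; c2 <- cand[ord[1], 2]
      # merge community c2 into c1
      E[c1, ] <- E[c1, ] + E[c2, ]
      E[, c1] <- E[, c1] + E[, c2]
      E <- E[-c2, -c2, drop = FALSE]
      a[c1] <- a[c1] + a[c2]
      a <- a[-c2]
      membership[membership == c2] <- c1
      membership[membership > c2] <- membership[membership > c2] - 1L
      cid[c1] <- min(cid[c1], cid[c2])
      cid <- cid[-c2]
    }
  } else if (!is.null(forceK)) {
    # no edges at all: merge lowest-index nodes until forceK remain
    membership <- pmin(seq_len(N), forceK)
  }

  labels <- as.integer(factor(membership, levels = unique(sort(membership))))
  names(labels) <- ids0
  new("CommunityPartition", labels = labels,
      nCommunities = length(unique(labels)),
      modularity = weightedModularity(W, labels))
}

#' @export
setMethod("communityLabels", "CommunityPartition", function(x) x@labels)
#' @export
setMethod("modularityScore", "CommunityPartition", function(x) x@modularity)
#' @export
setMethod("nNodes", "CommunityPartition", function(x) length(x@labels))

setMethod("show", "CommunityPartition", function(object) {
  cat("CommunityPartition:", object@nCommunities, "communities over",
      length(object@labels), "members, modularity =",
      signif(object@modularity, 5), "\n")
})

#' Misclassification rate of a partition against ground truth
#'
#' Matches detected communities to truth groups by the overlap-maximizing
#' one-to-one assignment (exact dynamic program over all assignments;
#' surplus communities or groups on either side stay unmatched) and returns
#' the fraction of members that do not sit in the community matched to
#' their true group — the "wrongly classified members / total members"
#' rate.
#'
#' @param pred a [CommunityPartition] or a named label vector.
#' @param truth named vector of ground-truth group labels over the same
#'   member set.
#' @return numeric in [0, 1].
#' @export
fdr <- function(pred, truth) {
  predLabels <- if (is(pred, "CommunityPartition")) pred@labels else pred
  if (is.null(names(predLabels)) || is.null(names(truth)))
    stop("pred and truth must be named by member id")
  if (!setequal(names(predLabels), names(truth)))
    stop("pred and truth must cover the same member set")
  truth <- truth[names(predLabels)]
  groups <- unique(truth)
  K <- length(groups)
  if (K > 10L) stop("more than 10 truth groups exceeds the exact matcher bound")
  comms <- unique(predLabels)
  ov <- vapply(groups, function(g)
    vapply(comms, function(c) sum(predLabels == c & truth == g), 0),
    numeric(length(comms)))
  ov <- matrix(ov, nrow = length(comms))   # communities x groups
  # dp over subsets of groups already matched; communities processed in turn
  nMask <- bitwShiftL(1L, K)
  dp <- rep(-Inf, nMask); dp[1] <- 0
  for (c in seq_len(nrow(ov))) {
    ndp <- dp
    for (mask in seq_len(nMask) - 1L) {
      if (!is.finite(dp[mask + 1L])) next
      for (g in seq_len(K)) {
        bit <- bitwShiftL(1L, g - 1L)
        if (bitwAnd(mask, bit) == 0L) {
          nm <- bitwOr(mask, bit)
          v <- dp[mask + 1L] + ov[c, g]
          if (v > ndp[nm + 1L]) ndp[nm + 1L] <- v
        }
      }
    }
    dp <- ndp
  }
  1 - max(dp) / length(predLabels)
}

#' Threshold sweep: links, density and communities versus t_m
#'
#' Applies each threshold in \code{grid} to the network, counts surviving
#' links and density, and runs [cnmCommunities()] on the surviving weighted
#' graph.
#'
#' @param net a [ReconstructedNetwork].
#' @param grid numeric thresholds in [0, 1].
#' @param forceK optional forced community count passed through.
#' @return data.frame with columns \code{t_m}, \code{link_count},
#'   \code{density}, \code{n_communities}, \code{modularity}.
#' @export
thresholdSweep <- function(net, grid = seq(0, 1, by = 0.05), forceK = NULL) {
  stopifnot(is(net, "ReconstructedNetwork"))
  if (!length(grid)) stop("grid must be non-empty")
  if (any(grid < 0 | grid > 1)) stop("grid values must lie in [0, 1]")
  rows <- lapply(grid, function(tm) {
    th <- thresholdNetwork(net, tm)
    met <- networkMetrics(th, tm)
    part <- cnmCommunities(th, forceK = forceK)
    data.frame(t_m = tm, link_count = met$linkCount, density = met$density,
               n_communities = part@nCommunities,
               modularity = part@modularity)
  })
  do.call(rbind, rows)
}
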