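#' Settings for the senate-like affiliation generator
#'
#' Defaults emulate the published statistics of the study system: 338
#' members, 3100 activities (bills), about 8 active members per activity,
#' 5 planted groups (two alliances of two parties each plus a mixed group).
#'
#' @param nMembers member count.
#' @param nActivities activity count.
#' @param meanActive mean participants per activity; realized counts are
#'   1 + Poisson(meanActive - 1), so every activity has at least one
#'   sponsor.
#' @param nGroups planted group count.
#' @param groupWeights relative group sizes (normalized internally). The
#'   default for 5 groups, (0.33, 0.15, 0.27, 0.13, 0.12), gives two large
#'   parties each flanked by a smaller ally plus a mixed group; other
#'   \code{nGroups} default to equal sizes.
#' @param allianceMap integer alliance id per group; default for 5 groups is
#'   \code{c(1, 1, 2, 2, 3)} (two alliances + mixed), otherwise each group
#'   its own alliance.
#' @param withinGroupProb probability that an active slot is filled from the
#'   proposing group (0.8 by default).
#' @param seed integer seed.
#' @return a validated list of generator settings.
#' @export
senateLikeSpec <- function(nMembers = 338L, nActivities = 3100L,
                           meanActive = 8, nGroups = 5L,
                           groupWeights = NULL, allianceMap = NULL,
                           withinGroupProb = 0.8, seed = 1L) {
  if (meanActive >= nMembers) stop("meanActive must be < nMembers")
  if (withinGroupProb < 0 || withinGroupProb > 1)
    stop("withinGroupProb must lie in [0, 1]")
  if (is.null(groupWeights))
    groupWeights <- if (nGroups == 5L) c(0.33, 0.15, 0.27, 0.13, 0.12)
                    else rep(1 / nGroups, nGroups)
  if (length(groupWeights) != nGroups) stop("one weight per group required")
  if (is.null(allianceMap))
    allianceMap <- if (nGroups == 5L) c(1L, 1L, 2L, 2L, 3L)
                   else seq_len(nGroups)
  if (length(allianceMap) != nGroups) stop("one alliance per group required")
  list(nMembers = as.integer(nMembers), nActivities = as.integer(nActivities),
       meanActive = meanActive, nGroups = as.integer(nGroups),
       groupWeights = groupWeights / sum(groupWeights),
       allianceMap = as.integer(allianceMap),
       withinGroupProb = withinGroupProb, seed = as.integer(seed))
}

# Largest-remainder apportionment of n into parts proportional to w.
apportion <- function(n, w) {
  raw <- n * w / sum(w)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a senate-like affiliation matrix with planted groups
#'
#' Each activity draws a proposing group (probability proportional to group
#' size), a participant count \eqn{n_\mu \sim 1 + \mathrm{Pois}(\bar n - 1)}
#' (clipped to the member count with a warning if ever exceeded), and its
#' participants without replacement: each slot comes from the proposing
#' group with probability \code{withinGroupProb}, otherwise from the rest of
#' the chamber. Deterministic under the settings' seed.
#'
#' @param spec a [senateLikeSpec()] list.
#' @return list with \code{affiliation} (an [AffiliationMatrix]),
#'   \code{groups} and \code{alliances} (named integer truth labels per
#'   member).
#' @export
generateAffiliation <- function(spec = senateLikeSpec()) {
  N <- spec$nMembers; M <- spec$nActivities
  sizes <- apportion(N, spec$groupWeights)
  groups <- rep(seq_len(spec$nGroups), sizes)
  withSeed(spec$seed, {
    A <- matrix(0, N, M)
    grpMembers <- split(seq_len(N), groups)
    nmu <- 1L + stats::rpois(M, spec$meanActive - 1)
    if (any(nmu > N)) {
      warning("participant draw exceeded member count; clipped")
      nmu <- pmin(nmu, N)
    }
    proposer <- sample.int(spec$nGroups, M, replace = TRUE,
                           prob = sizes / N)
    for (mu in seq_len(M)) {
      g <- proposer[mu]
      inG <- grpMembers[[g]]
      outG <- setdiff(seq_len(N), inG)
      k <- nmu[mu]
      kIn <- stats::rbinom(1L, k, spec$withinGroupProb)
      kIn <- min(kIn, length(inG))
      kOut <- min(k - kIn, length(outG))
      part <- c(if (kIn > 0) sample(inG, kIn),
                if (kOut > 0) sample(outG, kOut))
      A[part, mu] <- 1
    }
    aff <- affiliationMatrix(A)
    names(groups) <- aff@memberIds
    alliances <- spec$allianceMap[groups]
    names(alliances) <- aff@memberIds
    list(affiliation = aff, groups = groups, alliances = alliances)
  })
}

#' Generate a Potts model with planted random edges
#'
#' A uniformly random simple graph with \code{nEdges} edges; each edge's
#' interaction sub-block (entries with \eqn{k, l \ge 1}) is filled with
#' \eqn{\pm} \code{couplingScale} chosen by fair coin per entry. Field
#' (\eqn{(k,0)}/\eqn{(0,l)}) terms are zero. The benchmark for
#' planted-edge recovery.
#'
#' @param N node count.
#' @param Q state count.
#' @param nEdges edge count, at most \eqn{N(N-1)/2}.
#' @param couplingScale magnitude of every interaction entry.
#' @param seed integer seed.
#' @return list with \code{model} (a [PottsModel]) and \code{edges} (the
#'   true edge matrix, i < j).
#' @export
generatePlantedPotts <- function(N, Q, nEdges, couplingScale = 0.8,
                                 seed = 1L) {
  allPairs <- canonicalPairs(N)
  if (nEdges > nrow(allPairs)) stop("nEdges exceeds N(N-1)/2")
  withSeed(seed, {
    pick <- sort(sample.int(nrow(allPairs), nEdges))
    edges <- allPairs[pick, , drop = FALSE]
    couplings <- lapply(seq_len(nEdges), function(r) {
      blk <- matrix(0, Q, Q)
      blk[2:Q, 2:Q] <- couplingScale *
        sample(c(-1, 1), (Q - 1)^2, replace = TRUE)
      blk
    })
    list(model = pottsModel(N, Q, edges, couplings), edges = edges)
  })
}

#' Named fixture presets
#'
#' \describe{
#'   \item{senate-like}{[generateAffiliation()] at default spec.}
#'   \item{two-blocks}{a 40-member, 400-activity affiliation with two
#'     planted groups and strong within-group participation — a clean
#'     two-community benchmark.}
#'   \item{chain3}{a 3-node, Q = 2 Potts chain with ferromagnetic blocks
#'     (\eqn{J^{(1,1)} = -1}) on edges 1-2 and 2-3.}
#' }
#'
#' @param name preset name.
#' @param seed integer seed (affiliation presets).
#' @return the preset object (see Details).
#' @export
fixturePreset <- function(name = c("senate-like", "two-blocks", "chain3"),
                          seed = 1L) {
  name <- match.arg(name)
  switch(name,
    "senate-like" = generateAffiliation(senateLikeSpec(seed = seed)),
    "two-blocks" = generateAffiliation(senateLikeSpec(
      nMembers = 40L, nActivities = 400L, meanActive = 5, nGroups = 2L,
      groupWeights = c(0.5, 0.5), allianceMap = c(1L, 2L),
      withinGroupProb = 0.9, seed = seed)),
    "chain3" = {
      J <- matrix(0, 2, 2); J[2, 2] <- -1
      list(model = pottsModel(3, 2, rbind(c(1, 2), c(2, 3)), list(J, J)),
           edges = rbind(c(1L, 2L), c(2L, 3L)))
    })
}
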