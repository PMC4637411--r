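#' End-to-end network reconstruction strategies
#'
#' Runs one of the observation-building strategies from a binary affiliation
#' matrix through moments, coupling inversion and edge intensities:
#' \describe{
#'   \item{pure-observational}{states assigned directly from the affiliation
#'     ([assignStates()]), uniform sample averages, inversion with
#'     \code{excludeInactive = TRUE} (correlations carried by the shared
#'     inactive state are dropped, the necessity at small Q). A constant
#'     alpha of 0.01 is recorded in the metadata as the scheme tag.}
#'   \item{semi-observational}{states assigned from the affiliation, but
#'     sample averages reweighted by each observation's probability under
#'     the alpha generative model ([generativeWeights()]).}
#'   \item{generative}{the alpha matrix alone defines a same-state
#'     attraction Potts model; observations are Gibbs-sampled from it
#'     ([sampleFromAlpha()], 100,000 samples by default) and averaged
#'     uniformly.}
#'   \item{baseline}{no Potts machinery: a standard one-mode projection
#'     ([projectOneMode()], Jaccard by default) min-max normalized into a
#'     [ReconstructedNetwork].}
#' }
#'
#' @param aff an [AffiliationMatrix].
#' @param strategy one of \code{"pure-observational"},
#'   \code{"semi-observational"}, \code{"generative"}, \code{"baseline"}.
#' @param Q state count (ignored by the baseline).
#' @param alphaScheme \code{"liu"}, \code{"frequentist"},
#'   \code{"activity_adjusted"} or \code{"constant:<value>"}; the weighting
#'   used by the generative / semi-observational strategies.
#' @param baselineScheme projection scheme for \code{strategy = "baseline"}.
#' @param smoothing marginal-table floor passed to [marginalTables()].
#' @param nSamples Gibbs samples for the generative strategy.
#' @param seed integer seed; per-stage seeds are derived from it.
#' @param tm optional threshold applied to the result.
#' @return a [ReconstructedNetwork] whose \code{meta} records every
#'   parameter of the run.
#' @export
reconstructNetwork <- function(aff,
                               strategy = c("pure-observational",
                                            "semi-observational",
                                            "generative", "baseline"),
                               Q = 2L,
                               alphaScheme = "frequentist",
                               baselineScheme = "jaccard",
                               smoothing = 1e-6,
                               nSamples = 100000L,
                               seed = 1L,
                               tm = NULL) {
  stopifnot(is(aff, "AffiliationMatrix"))
  strategy <- match.arg(strategy)
  N <- nNodes(aff)
  meta <- list(strategy = strategy, Q = as.integer(Q), seed = as.integer(seed),
               smoothing = smoothing, alphaScheme = alphaScheme)

  if (strategy == "baseline") {
    W <- projectOneMode(aff, baselineScheme)
    pairs <- canonicalPairs(N)
    raw <- W[cbind(pairs[, 1], pairs[, 2])]
    rng <- range(raw)
    normd <- if (rng[2] > rng[1]) (raw - rng[1]) / (rng[2] - rng[1])
             else rep(0, length(raw))
    net <- new("ReconstructedNetwork",
               intensity = pairsToMatrix(normd, pairs, N),
               rawIntensity = pairsToMatrix(raw, pairs, N),
               adjacency = matrix(FALSE, N, N), tm = NA_real_,
               memberIds = aff@memberIds,
               meta = c(meta[names(meta) != "alphaScheme"],
                        list(baselineScheme = baselineScheme,
                             normalization = "minmax")))
    if (!is.null(tm)) net <- thresholdNetwork(net, tm)
    return(net)
  }

  makeAlpha <- function() {
    if (startsWith(alphaScheme, "constant")) {
      val <- suppressWarnings(as.numeric(sub("^constant:?", "", alphaScheme)))
      if (is.na(val)) val <- 0.01
      alphaConstant(N, val)
    } else switch(alphaScheme,
      liu = alphaLiu(aff),
      frequentist = alphaFrequentist(aff),
      activity_adjusted = alphaActivityAdjusted(aff),
      stop("unknown alpha scheme: ", alphaScheme))
  }

  basis <- chebyshevBasis(Q)
  excludeInactive <- FALSE

  if (strategy == "generative") {
    alpha <- makeAlpha()
    cfg <- samplerConfig(nSamples = nSamples,
                         seed = deriveSeed(seed, 2L))
    D <- sampleFromAlpha(alpha, Q, cfg)
    mom <- empiricalMoments(D, basis)
    meta$nSamples <- cfg$nSamples
    meta$avgAlpha <- mean(alpha@entries[upper.tri(alpha@entries)])
  } else {
    D <- assignStates(aff, Q, seed = deriveSeed(seed, 1L))
    if (strategy == "semi-observational") {
      alpha <- makeAlpha()
      w <- generativeWeights(D, alpha)
      mom <- empiricalMoments(D, basis, weights = w)
      meta$avgAlpha <- mean(alpha@entries[upper.tri(alpha@entries)])
    } else {                              # pure-observational
      mom <- empiricalMoments(D, basis)
      excludeInactive <- TRUE
      meta$alphaScheme <- "constant:0.01"
      meta$avgAlpha <- 0.01
    }
    meta$nSamples <- nrow(D@states)
  }

  mt <- marginalTables(mom, basis, smoothing = smoothing)
  cs <- invertCouplings(mt, basis, excludeInactive = excludeInactive)
  net <- edgeIntensities(cs, memberIds = aff@memberIds, meta = meta)
  if (!is.null(tm)) net <- thresholdNetwork(net, tm)
  net
}
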