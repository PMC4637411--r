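#' Sampler configuration
#'
#' Defaults mirror the generative strategy's sampling scale: 100,000 kept
#' samples, 1,000 burn-in sweeps, thinning 5.
#'
#' @param nSamples kept samples, >= 1.
#' @param burnIn discarded initial sweeps, >= 0.
#' @param thin sweeps between kept samples, >= 1.
#' @param seed integer RNG seed.
#' @return a list of validated sampler settings.
#' @export
samplerConfig <- function(nSamples = 100000L, burnIn = 1000L, thin = 5L,
                          seed = 1L) {
  if (nSamples < 1L) stop("nSamples must be >= 1")
  if (burnIn < 0L) stop("burnIn must be >= 0")
  if (thin < 1L) stop("thin must be >= 1")
  list(nSamples = as.integer(nSamples), burnIn = as.integer(burnIn),
       thin = as.integer(thin), seed = as.integer(seed))
}

# Shared driver: heat-bath Gibbs over explicit edge potential tables.
gibbsDriver <- function(N, Q, edges0, potRows, cfg, provenance) {
  if (nrow(edges0) == 0L) {
    # no interactions: direct uniform draws from the sampler's own stream
    states <- .gibbs_sample_cpp(N, Q, cfg$nSamples, 0L, 1L, cfg$seed,
                                matrix(integer(0), 0, 2),
                                matrix(numeric(0), 0, Q * Q))
  } else {
    states <- .gibbs_sample_cpp(N, Q, cfg$nSamples, cfg$burnIn, cfg$thin,
                                cfg$seed, edges0, potRows)
  }
  new("ObservationSet", states = states, Q = as.integer(Q),
      provenance = provenance)
}

#' Gibbs-sample configurations from a Potts model
#'
#' Single-site heat-bath (full conditional) updates in fixed node order
#' 1..N; one pass over all nodes is a sweep. The target is the model's
#' Boltzmann distribution \eqn{P(x) \propto \exp(-\mathcal{E}(x))}.
#' Identical seeds give identical samples on any platform.
#'
#' @param model a [PottsModel].
#' @param cfg a [samplerConfig()] list.
#' @return an [ObservationSet] with \code{cfg$nSamples} rows.
#' @export
gibbsSample <- function(model, cfg = samplerConfig()) {
  stopifnot(is(model, "PottsModel"))
  basis <- chebyshevBasis(model@Q)
  E <- nrow(model@edges)
  pot <- matrix(0, E, model@Q^2)
  for (r in seq_len(E))
    pot[r, ] <- as.vector(pairPotentialTable(model@couplings[[r]], basis))
  gibbsDriver(model@N, model@Q, model@edges - 1L, pot, cfg,
              sprintf("gibbs(N=%d,Q=%d,seed=%d)", model@N, model@Q, cfg$seed))
}

#' Sample from the alpha-parameterized generative Potts model
#'
#' Samples configurations from
#' \deqn{P(x) \propto \exp\Big[\tfrac{1}{2}\sum_i\sum_j \alpha_{ij}
#'   \delta(x_i, x_j)\Big]}
#' i.e. a Potts model in which pair \eqn{(i,j)} feels a same-state attraction
#' of strength \eqn{\alpha_{ij}}. \eqn{\delta} is the plain Kronecker delta
#' on equal states, so matching inactive states attract exactly as matching
#' active ones do; damping inactive matches is the role of the alpha scheme
#' upstream, not of this sampler.
#'
#' @param alpha an [AlphaMatrix] (or symmetric nonnegative matrix).
#' @param Q integer state count.
#' @param cfg a [samplerConfig()] list.
#' @return an [ObservationSet].
#' @export
sampleFromAlpha <- function(alpha, Q, cfg = samplerConfig()) {
  a <- if (is(alpha, "AlphaMatrix")) alpha@entries else as.matrix(alpha)
  if (!all(is.finite(a))) stop("alpha must be finite")
  if (max(abs(a - t(a))) > 1e-12) stop("alpha must be symmetric")
  N <- nrow(a)
  pr <- canonicalPairs(N)
  av <- a[pr]
  keep <- av != 0
  pr <- pr[keep, , drop = FALSE]; av <- av[keep]
  Q <- as.integer(Q)
  # pair potential H(s, t) = -alpha_ij * delta(s, t): each edge's table is
  # the scaled negative identity, flattened x_i fastest.
  eye <- as.vector(diag(Q))
  pot <- -outer(av, eye)
  gibbsDriver(N, Q, pr - 1L, pot, cfg,
              sprintf("alpha-generative(Q=%d,seed=%d)", Q, cfg$seed))
}

#' @export
setMethod("stateMatrix", "ObservationSet", function(x) x@states)
#' @export
setMethod("nStates", "ObservationSet", function(x) x@Q)
#' @export
setMethod("nNodes", "ObservationSet", function(x) ncol(x@states))

setMethod("show", "ObservationSet", function(object) {
  cat("ObservationSet:", nrow(object@states), "samples x",
      ncol(object@states), "nodes, Q =", object@Q,
      "[", object@provenance, "]\n")
})
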