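#' @import methods
NULL

## Central containers. All matrices are plain base matrices; sparsity never
## pays off at the Q <= 40, N <= ~400 scales the model targets.

#' Discrete orthonormal polynomial basis on \{0..Q-1\}
#'
#' The Gram (discrete Chebyshev) polynomials, orthonormalized under the
#' counting measure on the integer grid \eqn{\{0, \dots, Q-1\}}:
#' \eqn{\sum_x \Phi_k(x)\Phi_l(x) = \delta_{kl}}, with
#' \eqn{\Phi_0(x) = 1/\sqrt{Q}} and \eqn{\sum_x \Phi_k(x) = 0} for
#' \eqn{k \ge 1}. Row \eqn{k+1} of \code{values} holds \eqn{\Phi_k} evaluated
#' on the grid; the leading coefficient of each polynomial is fixed positive,
#' which makes the basis unique.
#'
#' @slot Q integer, number of states (>= 2).
#' @slot values Q x Q numeric matrix, \code{values[k + 1, x + 1]} =
#'   \eqn{\Phi_k(x)}.
#' @seealso [chebyshevBasis()]
#' @export
setClass("ChebyshevBasis",
  representation(Q = "integer", values = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(object@Q) != 1L || object@Q < 2L)
      msg <- c(msg, "Q must be a single integer >= 2")
    if (!all(dim(object@values) == c(object@Q, object@Q)))
      msg <- c(msg, "values must be a Q x Q matrix")
    G <- tcrossprod(object@values)
    if (max(abs(G - diag(object@Q))) > 1e-8)
      msg <- c(msg, "basis rows are not orthonormal")
    if (length(msg)) msg else TRUE
  })

#' Q-state Potts model on an explicit edge set
#'
#' Pairwise Markov random field over \code{N} nodes each taking one of
#' \code{Q} states. Each edge carries a Q x Q coupling block
#' \eqn{J_{(i,j)}^{(k,l)}} in the polynomial basis (entry \code{[k+1, l+1]});
#' the \eqn{(0,0)} entry is the absorbed constant and is fixed to zero.
#' Node pairs absent from \code{edges} have implicit zero blocks. The
#' configuration probability is \eqn{P(x) \propto \exp(-\mathcal{E}(x))}
#' with \eqn{\mathcal{E}} the sum of pair potentials over edges (see
#' [pottsEnergy()]); the conventional minus sign of the ferromagnetic energy
#' is carried inside the stored coupling values.
#'
#' @slot N integer, node count.
#' @slot Q integer, state count.
#' @slot edges two-column integer matrix of 1-based node pairs, i < j.
#' @slot couplings list of Q x Q numeric blocks, parallel to rows of
#'   \code{edges}.
#' @seealso [pottsModel()], [pottsEnergy()], [exactDistribution()]
#' @export
setClass("PottsModel",
  representation(N = "integer", Q = "integer", edges = "matrix",
                 couplings = "list"),
  validity = function(object) {
    msg <- character()
    e <- object@edges
    if (ncol(e) != 2L) msg <- c(msg, "edges must have two columns")
    if (nrow(e)) {
      if (any(e[, 1] >= e[, 2])) msg <- c(msg, "edges must satisfy i < j")
      if (any(e < 1) || any(e > object@N))
        msg <- c(msg, "edge endpoints out of range")
      if (anyDuplicated(paste(e[, 1], e[, 2])))
        msg <- c(msg, "duplicate edges")
    }
    if (length(object@couplings) != nrow(e))
      msg <- c(msg, "one coupling block per edge required")
    for (blk in object@couplings) {
      if (!all(dim(blk) == c(object@Q, object@Q))) {
        msg <- c(msg, "coupling blocks must be Q x Q"); break
      }
      if (!all(is.finite(blk))) { msg <- c(msg, "non-finite coupling"); break }
      if (blk[1L, 1L] != 0) {
        msg <- c(msg, "block (0,0) entry must be 0 (absorbed constant)"); break
      }
    }
    if (length(msg)) msg else TRUE
  })

#' Set of discrete-state observations
#'
#' \code{M} observed configurations ("snapshots") of \code{N} nodes, states
#' in \eqn{\{0, \dots, Q-1\}}; one row per observation. Carries a provenance
#' tag naming the strategy (and seed) that produced it.
#'
#' @slot states M x N integer matrix, entries in 0..Q-1.
#' @slot Q integer, state count.
#' @slot provenance character tag (e.g. \code{"assigned(Q=5,seed=1)"}).
#' @seealso [assignStates()], [gibbsSample()]
#' @export
setClass("ObservationSet",
  representation(states = "matrix", Q = "integer", provenance = "character"),
  validity = function(object) {
    s <- object@states
    if (length(s) && (min(s) < 0L || max(s) >= object@Q))
      return("states must lie in 0..Q-1")
    TRUE
  })

#' Binary member-by-activity affiliation matrix
#'
#' Two-mode participation table: \code{entries[i, mu] = 1} when member
#' \code{i} took part in activity \code{mu} (e.g. co-sponsored bill
#' \code{mu}). Activities with no participants are tolerated (a warning is
#' raised at construction) and skipped by the co-occurrence weightings.
#'
#' @slot entries N x M binary matrix (members x activities).
#' @slot memberIds character vector of row ids.
#' @slot activityIds character vector of column ids.
#' @seealso [affiliationMatrix()], [assignStates()], [projectOneMode()]
#' @export
setClass("AffiliationMatrix",
  representation(entries = "matrix", memberIds = "character",
                 activityIds = "character"),
  validity = function(object) {
    msg <- character()
    if (!all(object@entries %in% c(0, 1)))
      msg <- c(msg, "entries must be binary")
    if (length(object@memberIds) != nrow(object@entries))
      msg <- c(msg, "memberIds length must match rows")
    if (length(object@activityIds) != ncol(object@entries))
      msg <- c(msg, "activityIds length must match columns")
    if (length(msg)) msg else TRUE
  })

#' Preliminary pairwise interaction guesses (alpha)
#'
#' Symmetric nonnegative N x N matrix of co-occurrence-based interaction
#' strengths used by the generative and semi-observational strategies, with
#' a tag naming the weighting scheme that produced it.
#'
#' @slot entries N x N symmetric nonnegative matrix, zero diagonal.
#' @slot scheme one of \code{"liu"}, \code{"frequentist"},
#'   \code{"activity_adjusted"}, \code{"constant:<value>"}.
#' @seealso [alphaLiu()], [alphaFrequentist()], [alphaActivityAdjusted()]
#' @export
setClass("AlphaMatrix",
  representation(entries = "matrix", scheme = "character"),
  validity = function(object) {
    a <- object@entries
    msg <- character()
    if (nrow(a) != ncol(a)) msg <- c(msg, "entries must be square")
    if (!all(is.finite(a))) msg <- c(msg, "entries must be finite")
    else {
      if (max(abs(a - t(a))) > 1e-12) msg <- c(msg, "entries must be symmetric")
      if (min(a) < 0) msg <- c(msg, "entries must be nonnegative")
      if (any(diag(a) != 0)) msg <- c(msg, "diagonal must be zero")
    }
    if (length(msg)) msg else TRUE
  })

#' Sample moments of the basis polynomials
#'
#' First moments \eqn{\langle\Phi_k(x_i)\rangle_D} (k >= 1) and, per node
#' pair i < j, second moments \eqn{\langle\Phi_k(x_i)\Phi_l(x_j)\rangle_D},
#' averaged with either uniform or supplied sample weights. Pairs are stored
#' in the canonical i < j order of \code{pairs}; the second-moment matrix has
#' one row per pair and the (k, l) index flattened with k fastest.
#'
#' @slot first N x (Q-1) matrix, column k = \eqn{\langle\Phi_k\rangle}.
#' @slot second npairs x (Q-1)^2 matrix.
#' @slot pairs npairs x 2 integer matrix of 1-based pairs, i < j.
#' @slot Q integer.
#' @slot weighting character, \code{"uniform"} or \code{"weighted"}.
#' @seealso [empiricalMoments()], [marginalTables()]
#' @export
setClass("MomentSet",
  representation(first = "matrix", second = "matrix", pairs = "matrix",
                 Q = "integer", weighting = "character"))

#' Single-site and pairwise marginal tables
#'
#' Marginal probability tables reconstructed from a [MomentSet] by the
#' polynomial expansion, clipped below at the smoothing floor and
#' renormalized. \code{pair[p, ]} is the Q x Q table of pair
#' \code{pairs[p, ]} flattened with the first node's state fastest; use
#' [pairMarginal()] to extract one table in matrix form.
#'
#' @slot single N x Q matrix of single-site tables (rows sum to 1).
#' @slot pair npairs x Q^2 matrix of pairwise tables (rows sum to 1).
#' @slot pairs npairs x 2 integer matrix, i < j.
#' @slot Q integer.
#' @slot smoothing numeric floor applied before renormalization.
#' @seealso [marginalTables()], [invertCouplings()]
#' @export
setClass("MarginalTables",
  representation(single = "matrix", pair = "matrix", pairs = "matrix",
                 Q = "integer", smoothing = "numeric"))

#' Inverted coupling blocks for all node pairs
#'
#' Output of the closed-form Bethe inversion: one Q x Q coupling block per
#' node pair, stored as rows flattened with k fastest ((0,0) entry zero).
#' Use [couplingBlock()] to extract one block in matrix form.
#'
#' @slot blocks npairs x Q^2 matrix.
#' @slot pairs npairs x 2 integer matrix, i < j.
#' @slot Q integer.
#' @slot excludeInactive logical, whether state 0 was excluded from the
#'   inversion sums.
#' @seealso [invertCouplings()], [edgeIntensities()]
#' @export
setClass("CouplingSet",
  representation(blocks = "matrix", pairs = "matrix", Q = "integer",
                 excludeInactive = "logical"))

#' Reconstructed weighted network
#'
#' Symmetric edge-intensity matrix normalized to [0, 1] (min-max over the
#' off-diagonal pairs), the raw pre-normalization intensities, and the
#' boolean adjacency for the last threshold applied. \code{meta} records the
#' run parameters (strategy, Q, seed, smoothing, alpha scheme, ...).
#'
#' @slot intensity N x N symmetric matrix in [0, 1], zero diagonal.
#' @slot rawIntensity N x N symmetric matrix of raw scores.
#' @slot adjacency N x N logical matrix for threshold \code{tm}.
#' @slot tm numeric threshold last applied (NA before thresholding).
#' @slot memberIds character node ids.
#' @slot meta list of run metadata.
#' @seealso [edgeIntensities()], [thresholdNetwork()], [networkMetrics()]
#' @export
setClass("ReconstructedNetwork",
  representation(intensity = "matrix", rawIntensity = "matrix",
                 adjacency = "matrix", tm = "numeric",
                 memberIds = "character", meta = "list"),
  validity = function(object) {
    msg <- character()
    H <- object@intensity
    if (nrow(H) != ncol(H)) msg <- c(msg, "intensity must be square")
    else {
      if (max(abs(H - t(H))) > 1e-9) msg <- c(msg, "intensity must be symmetric")
      off <- H[upper.tri(H)]
      if (length(off) && (min(off) < -1e-12 || max(off) > 1 + 1e-12))
        msg <- c(msg, "normalized intensities must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
  })

#' Community partition of a network
#'
#' Node-to-community assignment with the (weighted) Newman modularity of the
#' partition on the graph it was computed from.
#'
#' @slot labels named integer vector, member id -> community id.
#' @slot nCommunities integer.
#' @slot modularity numeric in [-1, 1].
#' @seealso [cnmCommunities()], [fdr()]
#' @export
setClass("CommunityPartition",
  representation(labels = "integer", nCommunities = "integer",
                 modularity = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(unique(object@labels)) != object@nCommunities)
      msg <- c(msg, "nCommunities must match distinct labels")
    if (!is.na(object@modularity) &&
        (object@modularity < -1 - 1e-9 || object@modularity > 1 + 1e-9))
      msg <- c(msg, "modularity out of [-1, 1]")
    if (length(msg)) msg else TRUE
  })
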