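#' Standard one-mode projections of an affiliation matrix
#'
#' Pairwise member-member scores computed directly from the binary activity
#' profiles — the co-occurrence-counting family the statistical
#' reconstruction is compared against:
#' \describe{
#'   \item{jaccard}{\eqn{|i \cap j| / |i \cup j|} (0 when the union is
#'     empty); the usual choice for sparse affiliation data.}
#'   \item{matches}{number of activities on which the two profiles agree
#'     (both 1 or both 0).}
#'   \item{cross_product}{\eqn{|i \cap j|}, the plain co-occurrence count.}
#'   \item{covariance}{sample covariance of the two binary profiles.}
#'   \item{correlation}{Pearson correlation (0 when either profile is
#'     constant).}
#' }
#'
#' @param aff an [AffiliationMatrix].
#' @param scheme projection scheme name.
#' @return N x N symmetric numeric matrix with zero diagonal.
#' @export
projectOneMode <- function(aff, scheme = c("jaccard", "matches",
                                           "cross_product", "covariance",
                                           "correlation")) {
  stopifnot(is(aff, "AffiliationMatrix"))
  scheme <- match.arg(scheme)
  A <- aff@entries
  M <- ncol(A)
  r <- rowSums(A)
  inter <- tcrossprod(A)
  W <- switch(scheme,
    jaccard = {
      uni <- outer(r, r, "+") - inter
      out <- ifelse(uni > 0, inter / uni, 0)
      out
    },
    matches = M - (outer(r, r, "+") - 2 * inter),
    cross_product = inter,
    covariance = stats::cov(t(A)),
    correlation = {
      out <- suppressWarnings(stats::cor(t(A)))
      out[!is.finite(out)] <- 0
      out
    })
  diag(W) <- 0
  W
}

#' Basic metrics of a thresholded network
#'
#' @param net a [ReconstructedNetwork] or a symmetric numeric weight matrix.
#' @param tm threshold in [0, 1]; links are pairs with intensity strictly
#'   above it.
#' @return list with \code{linkCount}, \code{density} =
#'   \eqn{2 L / (N (N-1))}, \code{meanIntensityAll} (mean over all
#'   off-diagonal pairs) and \code{meanIntensityLinks} (mean over surviving
#'   links; 0 when there are none).
#' @export
networkMetrics <- function(net, tm = 0.5) {
  H <- if (is(net, "ReconstructedNetwork")) net@intensity else as.matrix(net)
  N <- nrow(H)
  if (N < 2L) stop("need at least two nodes")
  if (max(abs(H - t(H))) > 1e-9) stop("weight matrix must be symmetric")
  off <- H[upper.tri(H)]
  linked <- off > tm
  list(linkCount = sum(linked),
       density = 2 * sum(linked) / (N * (N - 1)),
       meanIntensityAll = mean(off),
       meanIntensityLinks = if (any(linked)) mean(off[linked]) else 0)
}
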