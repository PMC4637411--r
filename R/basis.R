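#' Build the discrete orthonormal polynomial basis on \{0..Q-1\}
#'
#' Orthonormalizes the monomials \eqn{1, x, x^2, \dots, x^{Q-1}} on the
#' integer grid \eqn{\{0, \dots, Q-1\}} under the plain counting measure,
#' yielding the Gram (discrete Chebyshev) polynomials \eqn{\Phi_k} with
#' \eqn{\sum_x \Phi_k(x) \Phi_l(x) = \delta_{kl}}. The leading coefficient of
#' each \eqn{\Phi_k} is fixed positive, making the basis unique. Under this
#' normalization the moment expansion of a histogram reproduces the histogram
#' exactly and the closed-form coupling inversion is an exact inverse of the
#' pair-potential expansion on an isolated pair.
#'
#' @param Q integer number of states, >= 2 (and <= 64; larger grids are out
#'   of the model's intended range and become numerically fragile).
#' @return a [ChebyshevBasis].
#' @examples
#' b <- chebyshevBasis(3)
#' basisValues(b)[2, ]          # Phi_1 on {0,1,2}: (-1, 0, 1)/sqrt(2)
#' tcrossprod(basisValues(b))   # identity
#' @export
chebyshevBasis <- function(Q) {
  if (!is.numeric(Q) || length(Q) != 1L || is.na(Q) || Q != round(Q) || Q < 2)
    stop("Q must be a single integer >= 2")
  if (Q > 64) stop("Q > 64 is out of range for this basis")
  Q <- as.integer(Q)
  x <- 0:(Q - 1L)
  # Stieltjes three-term recurrence: p_{k+1} ~ (x - a_k) p_k - b_k p_{k-1},
  # normalized at each step. Numerically stable where Gram-Schmidt on the
  # raw monomials is not (the Vandermonde matrix is severely
  # ill-conditioned already at moderate Q), and the positive normalization
  # keeps every leading coefficient positive.
  B <- matrix(0, Q, Q)
  B[1L, ] <- 1 / sqrt(Q)
  if (Q > 1L) {
    pkm1 <- rep(0, Q)
    pk <- B[1L, ]
    for (k in seq_len(Q - 1L)) {
      ak <- sum(x * pk^2)
      v <- (x - ak) * pk - if (k > 1L) sum(x * pk * pkm1) * pkm1 else 0
      # one explicit re-orthogonalization pass guards the recurrence
      for (j in seq_len(k)) v <- v - sum(v * B[j, ]) * B[j, ]
      nv <- sqrt(sum(v^2))
      v <- v / nv
      B[k + 1L, ] <- v
      pkm1 <- pk
      pk <- v
    }
  }
  new("ChebyshevBasis", Q = Q, values = B)
}

#' @describeIn chebyshevBasis basis value table (row k+1 = \eqn{\Phi_k}).
#' @param x a [ChebyshevBasis].
#' @export
setMethod("basisValues", "ChebyshevBasis", function(x) x@values)

#' @export
setMethod("nStates", "ChebyshevBasis", function(x) x@Q)

setMethod("show", "ChebyshevBasis", function(object) {
  cat("ChebyshevBasis: Q =", object@Q,
      "(orthonormal Gram polynomials on {0..", object@Q - 1, "})\n", sep = " ")
})

#' Evaluate the two-body pair potential of one coupling block
#'
#' Computes
#' \deqn{H_{(i,j)}(x_i, x_j) = \frac{1}{Q}\sum_{k\ge 1}\left[J^{(k,0)}
#'   \Phi_k(x_i) + J^{(0,k)} \Phi_k(x_j)\right] +
#'   \sum_{k,l} J^{(k,l)} \Phi_k(x_i) \Phi_l(x_j)}
#' with the \eqn{(0,0)} constant dropped. The double sum runs over all
#' \eqn{(k,l) \ne (0,0)}, so the mixed \eqn{(k,0)} terms contribute there as
#' well as through the explicit \eqn{1/Q}-weighted field terms.
#'
#' @param block Q x Q numeric coupling block (entry \code{[k+1, l+1]} =
#'   \eqn{J^{(k,l)}}; the \code{[1,1]} entry must be 0).
#' @param basis a [ChebyshevBasis] with matching Q.
#' @param xi,xj integer states in 0..Q-1 (vectors recycled elementwise).
#' @return numeric potential value(s).
#' @examples
#' b <- chebyshevBasis(2)
#' J <- matrix(0, 2, 2); J[2, 2] <- 1
#' pairPotential(J, b, 1, 1)  # Phi_1(1)^2 = 0.5
#' @export
pairPotential <- function(block, basis, xi, xj) {
  stopifnot(is(basis, "ChebyshevBasis"))
  Q <- basis@Q
  if (!all(dim(block) == c(Q, Q))) stop("block size must match basis Q")
  if (any(xi < 0 | xi >= Q | xj < 0 | xj >= Q))
    stop("state out of range 0..Q-1")
  H <- pairPotentialTable(block, basis)
  H[cbind(xi + 1L, xj + 1L)]
}

# Full Q x Q table H[x_i + 1, x_j + 1] for one block; workhorse for the
# energy, exact distribution and sampler.
pairPotentialTable <- function(block, basis) {
  Q <- basis@Q
  Phi <- basis@values                      # [k+1, x+1]
  A <- crossprod(Phi, block %*% Phi)       # sum_{k,l} J_kl Phi_k(x) Phi_l(y)
  fi <- drop(crossprod(Phi[-1L, , drop = FALSE], block[-1L, 1L])) / Q
  fj <- drop(crossprod(Phi[-1L, , drop = FALSE], block[1L, -1L])) / Q
  A + outer(fi, rep(1, Q)) + outer(rep(1, Q), fj)
}
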