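#' Construct a Potts model
#'
#' @param N integer node count.
#' @param Q integer state count (>= 2).
#' @param edges two-column matrix of node pairs (1-based). Pairs are
#'   canonicalized to i < j; duplicates are an error.
#' @param couplings list of Q x Q coupling blocks parallel to \code{edges}
#'   (entry \code{[k+1, l+1]} = \eqn{J^{(k,l)}}; the \code{[1,1]} constant
#'   entry is forced to 0).
#' @return a [PottsModel].
#' @examples
#' J <- matrix(0, 2, 2); J[2, 2] <- -1
#' m <- pottsModel(3, 2, rbind(c(1, 2), c(2, 3)), list(J, J))
#' pottsEnergy(m, c(1, 1, 1))
#' @export
pottsModel <- function(N, Q, edges = matrix(integer(0), 0, 2),
                       couplings = list()) {
  N <- as.integer(N); Q <- as.integer(Q)
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges)) {
    flip <- edges[, 1] > edges[, 2]
    edges[flip, ] <- edges[flip, 2:1]
    if (any(edges[, 1] == edges[, 2])) stop("self-loop edge not allowed")
  }
  couplings <- lapply(couplings, function(b) {
    b <- as.matrix(b); b[1L, 1L] <- 0; b
  })
  new("PottsModel", N = N, Q = Q, edges = edges, couplings = couplings)
}

#' @export
setMethod("nNodes", "PottsModel", function(x) x@N)
#' @export
setMethod("nStates", "PottsModel", function(x) x@Q)

setMethod("show", "PottsModel", function(object) {
  cat("PottsModel: N =", object@N, ", Q =", object@Q,
      ",", nrow(object@edges), "edges\n")
})

#' Energy of a configuration
#'
#' Returns \eqn{\mathcal{E}(x) = \sum_{(i,j) \in E} H_{(i,j)}(x_i, x_j)},
#' the (negated) exponent of the Boltzmann weight: configuration probability
#' is proportional to \eqn{\exp(-\mathcal{E}(x))}. The conventional minus
#' sign of the ferromagnetic energy functional is absorbed into the stored
#' coupling values, so one sign convention holds everywhere in the package.
#'
#' @param model a [PottsModel].
#' @param x integer configuration of length N, states in 0..Q-1.
#' @return numeric scalar.
#' @export
pottsEnergy <- function(model, x) {
  stopifnot(is(model, "PottsModel"))
  if (length(x) != model@N) stop("configuration length must equal N")
  if (any(x < 0 | x >= model@Q)) stop("state out of range 0..Q-1")
  if (!nrow(model@edges)) return(0)
  basis <- chebyshevBasis(model@Q)
  e <- 0
  for (r in seq_len(nrow(model@edges))) {
    H <- pairPotentialTable(model@couplings[[r]], basis)
    e <- e + H[x[model@edges[r, 1]] + 1L, x[model@edges[r, 2]] + 1L]
  }
  e
}

#' Exact Boltzmann distribution of a small Potts model
#'
#' Enumerates all \eqn{Q^N} configurations and returns the normalized
#' distribution \eqn{P(x) \propto \exp(-\mathcal{E}(x))}, together with the
#' exact single-site and pairwise marginals obtained by summation. Guarded to
#' \eqn{Q^N \le 10^6}.
#'
#' @param model a [PottsModel].
#' @return list with \code{configs} (\eqn{Q^N} x N integer matrix),
#'   \code{prob} (probability vector), \code{single} (N x Q matrix of
#'   single-site marginals) and \code{pairTable(i, j)} (a function returning
#'   the exact Q x Q pairwise marginal of any node pair).
#' @export
exactDistribution <- function(model) {
  stopifnot(is(model, "PottsModel"))
  N <- model@N; Q <- model@Q
  if (Q^N > 1e6) stop("Q^N exceeds the 1e6 enumeration guard")
  configs <- as.matrix(expand.grid(rep(list(0:(Q - 1L)), N)))
  dimnames(configs) <- NULL
  storage.mode(configs) <- "integer"
  basis <- chebyshevBasis(Q)
  energy <- numeric(nrow(configs))
  if (nrow(model@edges)) {
    for (r in seq_len(nrow(model@edges))) {
      H <- pairPotentialTable(model@couplings[[r]], basis)
      energy <- energy +
        H[cbind(configs[, model@edges[r, 1]] + 1L,
                configs[, model@edges[r, 2]] + 1L)]
    }
  }
  w <- exp(-(energy - min(energy)))
  prob <- w / sum(w)
  single <- vapply(seq_len(N), function(i)
    vapply(0:(Q - 1L), function(s) sum(prob[configs[, i] == s]), 0), numeric(Q))
  single <- t(single)
  pairTable <- function(i, j) {
    tab <- matrix(0, Q, Q)
    idx <- cbind(configs[, i] + 1L, configs[, j] + 1L)
    for (r in seq_along(prob)) tab[idx[r, 1], idx[r, 2]] <-
        tab[idx[r, 1], idx[r, 2]] + prob[r]
    tab
  }
  list(configs = configs, prob = prob, single = single, pairTable = pairTable)
}

#' Write / read a Potts model in the plain-text edge-block format
#'
#' Format: header line \code{potts N Q}; then, per edge, a line \code{i j}
#' (0-based node indices, i < j) followed by Q lines of Q floats giving the
#' coupling block row by row. Values are written with 17 significant digits
#' so a write/read round trip is bit-stable.
#'
#' @param model a [PottsModel].
#' @param path file path.
#' @return \code{writePottsModel} returns \code{path} invisibly;
#'   \code{readPottsModel} returns a [PottsModel].
#' @export
writePottsModel <- function(model, path) {
  stopifnot(is(model, "PottsModel"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("potts", model@N, model@Q), con)
  for (r in seq_len(nrow(model@edges))) {
    writeLines(paste(model@edges[r, 1] - 1L, model@edges[r, 2] - 1L), con)
    blk <- model@couplings[[r]]
    for (k in seq_len(model@Q))
      writeLines(paste(fmtNum(blk[k, ]), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname writePottsModel
#' @export
readPottsModel <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) != 3L || hdr[1] != "potts")
    stop("line 1: expected header 'potts N Q'")
  N <- as.integer(hdr[2]); Q <- as.integer(hdr[3])
  pos <- 2L
  edges <- NULL; couplings <- list()
  while (pos <= length(lines)) {
    ij <- suppressWarnings(as.integer(strsplit(trimws(lines[pos]), "\\s+")[[1]]))
    if (length(ij) != 2L || anyNA(ij))
      stop("line ", pos, ": expected an edge line 'i j'")
    if (pos + Q > length(lines))
      stop("line ", pos, ": truncated coupling block")
    blk <- t(vapply(seq_len(Q), function(k)
      as.numeric(strsplit(trimws(lines[pos + k]), "\\s+")[[1]]), numeric(Q)))
    edges <- rbind(edges, ij + 1L)
    couplings[[length(couplings) + 1L]] <- blk
    pos <- pos + Q + 1L
  }
  if (is.null(edges)) edges <- matrix(integer(0), 0, 2)
  pottsModel(N, Q, edges, couplings)
}
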