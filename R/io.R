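## File formats binding the pipeline into reproducible runs. All formats are
## plain text; readers validate and report offending line/column numbers.

#' Read / write an affiliation matrix
#'
#' Dense CSV/TSV layout: header row of activity ids, first column member
#' ids, binary entries. The delimiter is inferred from the file extension
#' (\code{.tsv} = tab, otherwise comma) or forced with \code{sep}.
#' MatrixMarket coordinate files (\code{.mtx}) are also read/written, with
#' sidecar id lists \code{<path>.members.txt} / \code{<path>.activities.txt}
#' (one id per line).
#'
#' @param path file path.
#' @param sep optional field separator override for the dense layout.
#' @return \code{readAffiliation} returns an [AffiliationMatrix];
#'   \code{writeAffiliation} returns \code{path} invisibly.
#' @export
readAffiliation <- function(path, sep = NULL) {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    mem <- readLines(paste0(path, ".members.txt"))
    act <- readLines(paste0(path, ".activities.txt"))
    if (length(mem) != nrow(m))
      stop("member sidecar has ", length(mem), " ids for ", nrow(m), " rows")
    if (length(act) != ncol(m))
      stop("activity sidecar has ", length(act), " ids for ", ncol(m),
           " columns")
    return(affiliationMatrix(m, mem, act))
  }
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, row.names = 1L)
  m <- as.matrix(df)
  bad <- which(!(m %in% c(0, 1)))
  if (length(bad)) {
    r <- (bad[1] - 1) %% nrow(m) + 1
    stop("non-binary entry at data row ", r, " (file line ", r + 1, ")")
  }
  affiliationMatrix(m, rownames(df), colnames(df))
}

#' @rdname readAffiliation
#' @param aff an [AffiliationMatrix].
#' @export
writeAffiliation <- function(aff, path, sep = NULL) {
  stopifnot(is(aff, "AffiliationMatrix"))
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(Matrix::Matrix(aff@entries, sparse = TRUE), path)
    writeLines(aff@memberIds, paste0(path, ".members.txt"))
    writeLines(aff@activityIds, paste0(path, ".activities.txt"))
    return(invisible(path))
  }
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- as.data.frame(aff@entries)
  colnames(df) <- aff@activityIds
  rownames(df) <- aff@memberIds
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Read / write observation samples as TSV
#'
#' One row per sample, one integer column per node, optional header line
#' \code{# potts-samples N Q seed}.
#'
#' @param path file path.
#' @param Q state count; required when the file has no header.
#' @return \code{readObservations} returns an [ObservationSet];
#'   \code{writeObservations} returns \code{path} invisibly.
#' @export
readObservations <- function(path, Q = NULL) {
  lines <- readLines(path)
  skip <- 0L
  if (length(lines) && startsWith(lines[1], "# potts-samples")) {
    hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    Q <- as.integer(hdr[4])
    skip <- 1L
  }
  if (is.null(Q)) stop("Q must be supplied when the file has no header")
  body <- lines[seq.int(skip + 1L, length.out = length(lines) - skip)]
  body <- body[nzchar(body)]
  rows <- strsplit(body, "\t", fixed = TRUE)
  ncols <- length(rows[[1]])
  states <- matrix(0L, length(rows), ncols)
  for (r in seq_along(rows)) {
    v <- suppressWarnings(as.integer(rows[[r]]))
    if (length(v) != ncols || anyNA(v))
      stop("line ", r + skip, ": expected ", ncols, " integer fields")
    states[r, ] <- v
  }
  new("ObservationSet", states = states, Q = as.integer(Q),
      provenance = paste0("file:", basename(path)))
}

#' @rdname readObservations
#' @param D an [ObservationSet].
#' @param seed seed recorded in the header (informational).
#' @export
writeObservations <- function(D, path, seed = NA) {
  stopifnot(is(D, "ObservationSet"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# potts-samples", ncol(D@states), D@Q, seed), con)
  utils::write.table(D@states, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read ground-truth labels
#'
#' Two-column CSV \code{member_id,group_id} (header optional, detected).
#'
#' @param path file path.
#' @return named vector of group labels.
#' @export
readLabels <- function(path) {
  df <- utils::read.csv(path, header = FALSE,
                        colClasses = "character")
  if (ncol(df) != 2L) stop("expected two columns (member_id, group_id)")
  if (identical(tolower(df[1, 1]), "member_id")) df <- df[-1, , drop = FALSE]
  labels <- df[[2]]
  names(labels) <- df[[1]]
  if (anyDuplicated(names(labels)))
    stop("duplicate member id at line ",
         which(duplicated(names(labels)))[1])
  labels
}

#' @rdname readLabels
#' @param labels named vector of labels.
#' @export
writeLabels <- function(labels, path) {
  utils::write.table(
    data.frame(member_id = names(labels), group_id = unname(labels)),
    path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a reconstructed network as a weighted edge list (TSV)
#'
#' Columns: member ids \code{i}, \code{j}, \code{raw} and \code{normalized}
#' intensities, and \code{linked} at the network's current threshold (NA
#' when un-thresholded).
#'
#' @param net a [ReconstructedNetwork].
#' @param path file path.
#' @param keepZero keep pairs with zero normalized intensity (default TRUE).
#' @return \code{path}, invisibly.
#' @export
writeEdgeList <- function(net, path, keepZero = TRUE) {
  stopifnot(is(net, "ReconstructedNetwork"))
  N <- nNodes(net)
  pairs <- canonicalPairs(N)
  idx <- cbind(pairs[, 1], pairs[, 2])
  df <- data.frame(i = net@memberIds[pairs[, 1]],
                   j = net@memberIds[pairs[, 2]],
                   raw = net@rawIntensity[idx],
                   normalized = net@intensity[idx],
                   linked = if (is.na(net@tm)) NA else net@adjacency[idx])
  if (!keepZero) df <- df[df$normalized > 0, ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a reconstructed network as GraphML
#'
#' Writes the weighted graph (all pairs with positive normalized intensity,
#' or only the surviving links when the network is thresholded) with a
#' \code{weight} edge attribute.
#'
#' @param net a [ReconstructedNetwork].
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
writeGraphML <- function(net, path) {
  stopifnot(is(net, "ReconstructedNetwork"))
  W <- survivingWeights(net)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a community partition as CSV
#'
#' Two columns: \code{member_id}, \code{community_id}.
#'
#' @param part a [CommunityPartition].
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
writePartition <- function(part, path) {
  stopifnot(is(part, "CommunityPartition"))
  utils::write.table(
    data.frame(member_id = names(part@labels),
               community_id = unname(part@labels)),
    path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write run metadata / metrics as JSON
#'
#' @param x named list.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
writeMetaJSON <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Keys mirror the CLI flags 1:1 (\code{strategy}, \code{q},
#' \code{alpha_scheme}, \code{t_m}, \code{smoothing}, \code{n_samples},
#' \code{seed}, io paths); CLI flags override file values.
#'
#' @param path YAML file path.
#' @return named list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping")
  cfg
}
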