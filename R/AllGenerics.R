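#' Number of nodes / members
#' @param x an object with a node dimension.
#' @return integer count.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' Number of states Q
#' @param x an object carrying a state count.
#' @return integer Q.
#' @export
setGeneric("nStates", function(x) standardGeneric("nStates"))

#' State matrix of an observation set
#' @param x an [ObservationSet].
#' @return M x N integer matrix with entries in 0..Q-1.
#' @export
setGeneric("stateMatrix", function(x) standardGeneric("stateMatrix"))

#' Normalized edge-intensity matrix
#' @param x a [ReconstructedNetwork].
#' @return N x N symmetric numeric matrix in [0, 1].
#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))

#' Boolean adjacency at the last threshold applied
#' @param x a [ReconstructedNetwork].
#' @return N x N logical matrix.
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' Community labels
#' @param x a [CommunityPartition].
#' @return named integer vector, member id -> community id.
#' @export
setGeneric("communityLabels", function(x) standardGeneric("communityLabels"))

#' Modularity score of a partition
#' @param x a [CommunityPartition].
#' @return numeric in [-1, 1].
#' @export
setGeneric("modularityScore", function(x) standardGeneric("modularityScore"))

#' Affiliation entries
#' @param x an [AffiliationMatrix].
#' @return N x M binary matrix (members x activities).
#' @export
setGeneric("affiliationEntries",
           function(x) standardGeneric("affiliationEntries"))

#' Alpha matrix entries
#' @param x an [AlphaMatrix].
#' @return N x N symmetric numeric matrix.
#' @export
setGeneric("alphaEntries", function(x) standardGeneric("alphaEntries"))

#' Basis value table
#' @param x a [ChebyshevBasis].
#' @return Q x Q matrix, row k+1 = polynomial k on the grid.
#' @export
setGeneric("basisValues", function(x) standardGeneric("basisValues"))
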