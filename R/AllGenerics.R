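#' @include AllClasses.R
NULL

#' Sum of absolute edge weights of a network
#'
#' Global strength — the connectivity measure compared by the network
#' comparison test — is the sum of \eqn{|w_{ij}|} over the upper triangle of
#' the weight matrix.
#'
#' @param x a \linkS4class{NetworkModel}, \linkS4class{TrueNetworkSpec} or
#'   plain symmetric weight matrix.
#' @return a single nonnegative number.
#' @examples
#' W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- 0.26
#' W[1, 3] <- W[3, 1] <- -0.18; W[2, 3] <- W[3, 2] <- 0.44
#' globalStrength(W)  # 0.88
#' @export
setGeneric("globalStrength", function(x) standardGeneric("globalStrength"))

#' Node strength centrality
#'
#' For each node, the sum of absolute weights of its incident edges, with
#' z-scores standardized across nodes (all zero when every strength is
#' equal), ranks, degree and degree fraction.
#'
#' @param x a \linkS4class{NetworkModel}, \linkS4class{TrueNetworkSpec} or
#'   weight matrix.
#' @return a \linkS4class{CentralityTable}.
#' @export
setGeneric("strengthCentrality",
           function(x) standardGeneric("strengthCentrality"))

#' Accessors for cytonet result objects
#'
#' Small accessor generics returning slot contents: \code{edgeWeights}
#' (weight matrix of a network), \code{nodeNames}, \code{truePartials} and
#' \code{precisionMatrix} (ground-truth or estimated matrices),
#' \code{communityLabels}, \code{csCoefficient}, and \code{edgeTable}
#' (tabular edge or centrality summaries).
#'
#' @param x a cytonet S4 object.
#' @param ... passed on to methods.
#' @return the slot contents.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("edgeWeights", function(x) standardGeneric("edgeWeights"))

#' @rdname accessors
#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))

#' @rdname accessors
#' @export
setGeneric("truePartials", function(x) standardGeneric("truePartials"))

#' @rdname accessors
#' @export
setGeneric("precisionMatrix", function(x) standardGeneric("precisionMatrix"))

#' @rdname accessors
#' @export
setGeneric("communityLabels", function(x) standardGeneric("communityLabels"))

#' @rdname accessors
#' @export
setGeneric("csCoefficient", function(x) standardGeneric("csCoefficient"))

#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))
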