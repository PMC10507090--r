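#' @include AllGenerics.R estimate.R
NULL

.weights_of <- function(x) {
  if (is(x, "NetworkModel")) return(x@weights)
  if (is(x, "TrueNetworkSpec")) return(x@truePartials)
  W <- as.matrix(x)
  if (!isTRUE(all.equal(W, t(W), tolerance = 1e-10)))
    stop("weight matrix must be symmetric")
  diag(W) <- 0
  W
}

#' @rdname globalStrength
#' @export
setMethod("globalStrength", "ANY", function(x) {
  W <- .weights_of(x)
  sum(abs(W[upper.tri(W)]))
})

#' @rdname strengthCentrality
#' @export
setMethod("strengthCentrality", "ANY", function(x) {
  W <- .weights_of(x)
  p <- ncol(W)
  nm <- colnames(W)
  if (is.null(nm)) nm <- paste0("V", seq_len(p))
  s <- rowSums(abs(W))
  sdev <- sd(s)
  z <- if (p > 1 && sdev > 0) (s - mean(s)) / sdev else rep(0, p)
  deg <- rowSums(abs(W) > 1e-10)
  tab <- S4Vectors::DataFrame(
    node = nm, strength = unname(s), z = unname(z),
    rank = as.integer(rank(-s, ties.method = "min")),
    degree = as.integer(deg),
    degreeFraction = round(100 * unname(deg) / (p - 1), 1))
  methods::new("CentralityTable", table = tab)
})

#' Percentage of possible partners a node is connected to
#'
#' \eqn{100 \times degree / (p - 1)}, reported to one decimal (e.g. 7 of a
#' possible 11 partners is 63.6).
#'
#' @param net a \linkS4class{NetworkModel}, \linkS4class{TrueNetworkSpec}
#'   or weight matrix (p >= 2).
#' @param node node name or index.
#' @return percentage to one decimal.
#' @examples
#' W <- matrix(0, 12, 12)
#' W[1, 2:8] <- W[2:8, 1] <- 0.1
#' degreeFraction(W, 1)  # 63.6
#' @export
degreeFraction <- function(net, node) {
  W <- .weights_of(net)
  p <- ncol(W)
  stopifnot(p >= 2)
  if (is.character(node)) node <- match(node, colnames(W))
  round(100 * sum(abs(W[node, ]) > 1e-10) / (p - 1), 1)
}

#' Select influential nodes from a centrality table
#'
#' Two interpretations of "top scoring" nodes are offered, since the field
#' criterion is verbal rather than numeric: \code{"z_threshold"} keeps
#' nodes with z-scored strength at or above \code{param} (default 1.0);
#' \code{"top_gap"} keeps the nodes above the largest gap in the sorted
#' z-score sequence (none when all z-scores are equal). An empty selection
#' is returned with a warning, not an error.
#'
#' @param tbl a \linkS4class{CentralityTable}.
#' @param rule \code{"z_threshold"} or \code{"top_gap"}.
#' @param param the z threshold (ignored by \code{"top_gap"}).
#' @return list with \code{nodes} (character vector), \code{rule},
#'   \code{param} and \code{zScores} of the selected nodes.
#' @export
selectInfluential <- function(tbl, rule = c("z_threshold", "top_gap"),
                              param = 1.0) {
  rule <- match.arg(rule)
  d <- tbl@table
  stopifnot(nrow(d) >= 2)
  if (rule == "z_threshold") {
    sel <- d$node[d$z >= param]
  } else {
    o <- order(d$z, decreasing = TRUE)
    zs <- d$z[o]
    gaps <- -diff(zs)
    if (max(gaps) <= 1e-12) {
      sel <- character()
    } else {
      k <- which.max(gaps)
      sel <- d$node[o][seq_len(k)]
    }
  }
  if (length(sel) == 0L)
    warning("influential-node selection is empty under rule '", rule, "'")
  list(nodes = sel, rule = rule, param = param,
       zScores = setNames(d$z[match(sel, d$node)], sel))
}

#' @rdname accessors
#' @export
setMethod("edgeTable", "CentralityTable", function(x) x@table)

#' @rdname accessors
#' @export
setMethod("as.data.frame", "CentralityTable",
          function(x, ...) as.data.frame(x@table))

setMethod("show", "CentralityTable", function(object) {
  d <- as.data.frame(object@table)
  d <- d[order(-d$strength), ]
  cat(sprintf("CentralityTable: %d nodes\n", nrow(d)))
  print(head(d, 10), row.names = FALSE)
})
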