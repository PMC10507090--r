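#' @include AllClasses.R cohort.R estimate.R
NULL

#' Write a cohort to CSV with a metadata sidecar
#'
#' The data file has one row per subject (header row = variable names, first
#' column = subject id); the sidecar CSV records each variable's role,
#' scale and instrument tag.
#'
#' @param x a \linkS4class{CohortTable}.
#' @param file data CSV path; the sidecar defaults to
#'   \code{<file>.meta.csv}.
#' @param metaFile sidecar path override.
#' @return \code{readCohortCSV} returns a \linkS4class{CohortTable}.
#' @export
writeCohortCSV <- function(x, file, metaFile = paste0(file, ".meta.csv")) {
  d <- data.frame(subject_id = subjectIds(x), cohortMatrix(x),
                  check.names = FALSE)
  write.csv(d, file, row.names = FALSE)
  meta <- data.frame(variable = rownames(x), role = rowData(x)$role,
                     scale = rowData(x)$scale,
                     instrument = rowData(x)$instrument)
  write.csv(meta, metaFile, row.names = FALSE)
  invisible(c(file, metaFile))
}

#' @rdname writeCohortCSV
#' @export
readCohortCSV <- function(file, metaFile = paste0(file, ".meta.csv")) {
  d <- read.csv(file, check.names = FALSE)
  meta <- read.csv(metaFile)
  X <- as.matrix(d[, -1, drop = FALSE])
  rownames(X) <- d[[1]]
  ord <- match(colnames(X), meta$variable)
  if (anyNA(ord)) stop("metadata sidecar does not cover all variables")
  CohortTable(X, roles = meta$role[ord], scales = meta$scale[ord],
              instruments = as.character(meta$instrument[ord]),
              subjectIds = d[[1]])
}

#' Serialize a network model
#'
#' \code{writeNetworkCSV} writes the full weight matrix;
#' \code{writeEdgeListTSV} a three-column weighted edge list of the nonzero
#' edges; \code{writeNetworkGraphML} a GraphML file (via igraph) with the
#' weight as an edge attribute; \code{networkPathJSON} the penalty-path
#' diagnostics as JSON.
#'
#' @param net a \linkS4class{NetworkModel}.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writeNetworkCSV <- function(net, file) {
  write.csv(net@weights, file, row.names = TRUE)
  invisible(file)
}

#' @rdname writeNetworkCSV
#' @export
writeEdgeListTSV <- function(net, file) {
  W <- net@weights
  idx <- which(upper.tri(W) & abs(W) > 1e-10, arr.ind = TRUE)
  d <- data.frame(node_a = net@nodeNames[idx[, 1]],
                  node_b = net@nodeNames[idx[, 2]],
                  weight = W[idx])
  write.table(d, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname writeNetworkCSV
#' @export
writeNetworkGraphML <- function(net, file) {
  g <- igraph::graph_from_adjacency_matrix(net@weights, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::write_graph(g, file, format = "graphml")
  invisible(file)
}

#' @rdname writeNetworkCSV
#' @export
networkPathJSON <- function(net, file = NULL) {
  x <- list(selected_lambda = net@selectedLambda, ebic_gamma = net@ebicGamma,
            lambdas = net@pathLambdas, ebics = net@pathEbics,
            edge_counts = net@pathEdgeCounts, edge_count = net@edgeCount,
            n = net@n, p = net@p)
  if (is.null(file)) return(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Serialize resampling and comparison results
#'
#' \code{writeBootstrapCSV} writes the per-edge summary table (endpoints,
#' observed weight, inclusion proportions, reliability flag);
#' \code{writeStabilityJSON} the CS-coefficient with its grid and
#' criterion; \code{writeNCTJSON} the comparison statistics, p-values and
#' (optionally) the permutation null draws.
#'
#' @param x a \linkS4class{BootstrapResult}, \linkS4class{StabilityResult}
#'   or \linkS4class{NCTResult}.
#' @param file output path.
#' @param includeNull for \code{writeNCTJSON}, include the permutation
#'   null distributions (default \code{FALSE}).
#' @return the file path, invisibly.
#' @export
writeBootstrapCSV <- function(x, file) {
  write.csv(as.data.frame(x@edges), file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeBootstrapCSV
#' @export
writeStabilityJSON <- function(x, file) {
  jsonlite::write_json(
    list(cs_coefficient = x@csCoefficient, drop_grid = x@dropGrid,
         cor_threshold = x@corThreshold, certainty = x@certainty,
         settings = x@settings, seed = x@seed),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname writeBootstrapCSV
#' @export
writeNCTJSON <- function(x, file, includeNull = FALSE) {
  out <- list(design = x@design, S = x@SObserved, M = x@MObserved,
              p_S = x@pS, p_M = x@pM, n_permutations = x@nPermutations,
              alpha = x@alpha, seed = x@seed,
              global_strength_A = globalStrength(x@networkA),
              global_strength_B = globalStrength(x@networkB))
  if (includeNull) out$null <- list(S = x@SNull, M = x@MNull)
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Write ground truth of a synthetic network to JSON
#' @param spec a \linkS4class{TrueNetworkSpec}.
#' @param file output path.
#' @export
writeTruthJSON <- function(spec, file) {
  jsonlite::write_json(
    list(n_vars = spec@nVars, topology = spec@topology,
         precision = spec@precision, true_partials = spec@truePartials,
         true_global_strength = globalStrength(spec),
         shrink = spec@shrink),
    file, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(file)
}
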