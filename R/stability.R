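#' @include AllGenerics.R estimate.R metrics.R
NULL

.edge_index <- function(nm) {
  p <- length(nm)
  ij <- which(upper.tri(diag(p)), arr.ind = TRUE)
  ij <- ij[order(ij[, 2], ij[, 1]), , drop = FALSE]  # column-major upper tri
  S4Vectors::DataFrame(from = nm[ij[, 1]], to = nm[ij[, 2]],
                       i = as.integer(ij[, 1]), j = as.integer(ij[, 2]))
}

.prep_boot_data <- function(data) {
  if (is(data, "CohortTable")) {
    X <- cohortMatrix(data)
    roles <- variableRoles(data)
    strata <- if (any(roles == "treatment"))
      X[, names(roles)[roles == "treatment"][1L]] else NULL
  } else {
    X <- as.matrix(data)
    strata <- NULL
  }
  cc <- complete.cases(X)
  list(X = X[cc, , drop = FALSE],
       strata = if (!is.null(strata)) strata[cc] else NULL)
}

#' Nonparametric bootstrap of edge weights
#'
#' Resamples subjects with replacement \code{B} times, re-estimates the
#' network with identical settings each time, and reports for every node
#' pair the proportion of bootstrap networks in which the edge was
#' estimated strictly above zero (the literal reliability rule for positive
#' associations; an edge is flagged reliable when this proportion is at
#' least 0.5) plus a sign-agnostic nonzero proportion for negative edges.
#' When a treatment node is present, resampling is stratified by arm to
#' preserve group sizes. Replicates whose estimation fails are skipped and
#' counted; more than 10\% failures aborts.
#'
#' @param data a \linkS4class{CohortTable} or subjects-by-variables matrix.
#' @param B bootstrap samples (>= 1; 1000 in the reference protocol).
#' @param gamma,nLambda,minRatio estimator settings (as in
#'   \code{\link{estimateNetwork}}).
#' @param seed integer RNG seed.
#' @return a \linkS4class{BootstrapResult}.
#' @export
edgeBootstrap <- function(data, B = 1000, gamma = 0, nLambda = 100,
                          minRatio = 0.01, seed = 1L) {
  stopifnot(B >= 1)
  pd <- .prep_boot_data(data)
  X <- pd$X
  n <- nrow(X); p <- ncol(X)
  nm <- colnames(X); if (is.null(nm)) nm <- paste0("V", seq_len(p))
  observed <- .estimate_weights(X, gamma, nLambda, minRatio)
  ei <- .edge_index(nm)
  ne <- nrow(ei)
  set.seed(as.integer(seed))
  samples <- matrix(NA_real_, B, ne)
  fails <- 0L
  for (b in seq_len(B)) {
    idx <- if (is.null(pd$strata)) {
      sample.int(n, n, replace = TRUE)
    } else {
      unlist(lapply(split(seq_len(n), pd$strata),
                    function(g) sample(g, length(g), replace = TRUE)),
             use.names = FALSE)
    }
    W <- tryCatch(.estimate_weights(X[idx, , drop = FALSE], gamma, nLambda,
                                    minRatio),
                  error = function(e) NULL)
    if (is.null(W)) { fails <- fails + 1L; next }
    samples[b, ] <- W[cbind(ei$i, ei$j)]
  }
  if (fails > 0.1 * B)
    stop(sprintf("bootstrap estimation failed in %d of %d replicates", fails, B))
  ok <- !is.na(samples[, 1L])
  samples <- samples[ok, , drop = FALSE]
  Beff <- nrow(samples)
  posProp <- colMeans(samples > 0)
  nzProp <- colMeans(abs(samples) > 1e-10)
  edges <- S4Vectors::DataFrame(
    ei, weight = observed[cbind(ei$i, ei$j)],
    positiveProportion = posProp, nonzeroProportion = nzProp,
    reliable = isReliableEdge(posProp))
  methods::new("BootstrapResult", B = as.integer(B),
               BEffective = as.integer(Beff), edges = edges,
               weightSamples = samples,
               settings = list(gamma = gamma, nLambda = nLambda,
                               minRatio = minRatio),
               seed = as.integer(seed))
}

#' Edge reliability rule
#'
#' An edge is considered reliably present when it was estimated above zero
#' in at least half of the nonparametric bootstrap samples; a proportion of
#' exactly 0.5 qualifies and 0.49 does not.
#'
#' @param proportion bootstrap inclusion proportion(s) in [0, 1].
#' @param threshold reliability cut-off (default 0.5).
#' @return logical vector.
#' @export
isReliableEdge <- function(proportion, threshold = 0.5) {
  proportion >= threshold
}

#' @rdname accessors
#' @export
setMethod("edgeTable", "BootstrapResult", function(x) x@edges)

setMethod("show", "BootstrapResult", function(object) {
  cat(sprintf("BootstrapResult: B = %d (%d effective), %d node pairs, %d reliable edges\n",
              object@B, object@BEffective, nrow(object@edges),
              sum(object@edges$reliable)))
})

#' Case-dropping subset bootstrap and the CS-coefficient
#'
#' For each case-drop proportion d in the grid, draws \code{B} subsamples
#' of \eqn{\lceil (1-d) n \rceil} subjects without replacement,
#' re-estimates the network, and correlates (Spearman) the subsample
#' strength centralities with the full-sample ones. The CS-coefficient is
#' the largest d at which at least \code{certainty} (default 95\%) of the
#' correlations reach \code{corThreshold} (default 0.70) — 0 when no level
#' qualifies. Values below 0.25 indicate unstable centralities; above 0.5
#' is ideal. Grid levels whose retained size falls below p + 1 are skipped
#' with a warning.
#'
#' @param data a \linkS4class{CohortTable} or subjects-by-variables matrix.
#' @param dropGrid case-drop proportions in (0, 0.95); default 0.05 to 0.75
#'   in steps of 0.10.
#' @param B subsamples per level (default 1000).
#' @param gamma,nLambda,minRatio estimator settings.
#' @param corThreshold,certainty stability criterion (0.70 / 0.95).
#' @param corMethod correlation between subsample and full-sample
#'   centralities. Default \code{"pearson"}, the convention of reference
#'   stability implementations: rank-based correlation degenerates on
#'   networks whose non-hub strengths are nearly exchangeable (their ranks
#'   are pure noise), understating stability.
#' @param seed integer RNG seed.
#' @return a \linkS4class{StabilityResult}.
#' @export
caseDroppingStability <- function(data, dropGrid = seq(0.05, 0.75, by = 0.10),
                                  B = 1000, gamma = 0, nLambda = 100,
                                  minRatio = 0.01, corThreshold = 0.70,
                                  certainty = 0.95,
                                  corMethod = c("pearson", "spearman"),
                                  seed = 1L) {
  corMethod <- match.arg(corMethod)
  stopifnot(all(dropGrid > 0), all(dropGrid < 0.95), B >= 1)
  pd <- .prep_boot_data(data)
  X <- pd$X
  n <- nrow(X); p <- ncol(X)
  full <- rowSums(abs(.estimate_weights(X, gamma, nLambda, minRatio)))
  set.seed(as.integer(seed))
  cors <- matrix(NA_real_, B, length(dropGrid))
  colnames(cors) <- as.character(dropGrid)
  for (k in seq_along(dropGrid)) {
    keep <- ceiling((1 - dropGrid[k]) * n)
    if (keep < p + 1) {
      warning(sprintf("drop level %.2f skipped: retained size %d < p + 1",
                      dropGrid[k], keep))
      next
    }
    for (b in seq_len(B)) {
      idx <- sample.int(n, keep)
      W <- tryCatch(.estimate_weights(X[idx, , drop = FALSE], gamma,
                                      nLambda, minRatio),
                    error = function(e) NULL)
      if (is.null(W)) next
      cors[b, k] <- suppressWarnings(
        cor(full, rowSums(abs(W)), method = corMethod))
    }
  }
  cs <- .cs_from_correlations(cors, dropGrid, corThreshold, certainty)
  methods::new("StabilityResult", dropGrid = dropGrid, correlations = cors,
               csCoefficient = cs, corThreshold = corThreshold,
               certainty = certainty,
               settings = list(gamma = gamma, nLambda = nLambda,
                               minRatio = minRatio, B = B,
                               corMethod = corMethod),
               seed = as.integer(seed))
}

# CS rule, exposed internally so boundary behaviour is testable on injected
# correlation draws: maximum grid proportion at which >= certainty of the
# subsample correlations reach the threshold; 0 when none does. Subsample
# correlations that are NA (degenerate subsamples) count as failures.
.cs_from_correlations <- function(cors, dropGrid, corThreshold, certainty) {
  passes <- vapply(seq_along(dropGrid), function(k) {
    v <- cors[, k]
    if (all(is.na(v))) return(FALSE)
    mean(!is.na(v) & v >= corThreshold) >= certainty
  }, logical(1))
  if (any(passes)) max(dropGrid[passes]) else 0
}

#' @rdname accessors
#' @export
setMethod("csCoefficient", "StabilityResult", function(x) x@csCoefficient)

setMethod("show", "StabilityResult", function(object) {
  cat(sprintf(
    "StabilityResult: CS-coefficient = %.2f (criterion: %.0f%% of subsample correlations >= %.2f)\n",
    object@csCoefficient, 100 * object@certainty, object@corThreshold))
})
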