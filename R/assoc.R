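#' @include AllClasses.R cohort.R
NULL

#' Spearman correlation matrix of a cohort
#'
#' Rank correlations (average ranks for ties) are the association input to
#' network estimation: they are robust to the positive skew of cytokine
#' concentrations and natural for ordinal Likert items. Binary and
#' treatment columns are ranked like any other column.
#'
#' @param data a \linkS4class{CohortTable} or subjects-by-variables matrix.
#' @param missingPolicy \code{"complete_rows"} (default; drop subjects with
#'   any missing value) or \code{"pairwise"} (pairwise-complete
#'   correlations; \code{nEffective} records the minimum pairwise n).
#' @return a \linkS4class{CorrelationEstimate} (not yet PSD-repaired).
#' @examples
#' rankCorrelationMatrix(cbind(x = c(1, 2, 3), y = c(2, 1, 3)))@matrix
#' @export
rankCorrelationMatrix <- function(data,
                                  missingPolicy = c("complete_rows",
                                                    "pairwise")) {
  missingPolicy <- match.arg(missingPolicy)
  X <- if (is(data, "CohortTable")) cohortMatrix(data) else as.matrix(data)
  storage.mode(X) <- "double"
  if (missingPolicy == "complete_rows") {
    X <- X[complete.cases(X), , drop = FALSE]
    if (nrow(X) < 3) stop("fewer than 3 complete rows available")
    nEff <- nrow(X)
    const <- apply(X, 2, function(v) length(unique(v)) < 2L)
    if (any(const))
      stop("constant column(s): ", paste(colnames(X)[const], collapse = ", "))
    M <- cpp_spearman(X)
  } else {
    npair <- crossprod(!is.na(X))
    if (min(npair) < 3)
      stop("fewer than 3 usable rows for some variable pair")
    const <- apply(X, 2, function(v) length(unique(v[!is.na(v)])) < 2L)
    if (any(const))
      stop("constant column(s): ", paste(colnames(X)[const], collapse = ", "))
    nEff <- as.integer(min(npair))
    M <- cor(X, method = "spearman", use = "pairwise.complete.obs")
    M <- (M + t(M)) / 2
    diag(M) <- 1
  }
  dimnames(M) <- list(colnames(X), colnames(X))
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  methods::new("CorrelationEstimate", matrix = M,
               nEffective = as.integer(nEff), method = "spearman",
               psdRepaired = FALSE, minEigenvalueBefore = min(ev))
}

#' Repair a correlation matrix to positive semi-definiteness
#'
#' Pairwise Spearman matrices can be indefinite; LASSO estimation requires a
#' PSD input. Negative eigenvalues are clipped at zero and the diagonal is
#' renormalized to 1 in one pass. Inputs already PSD (within tolerance) are
#' returned unchanged, so the operation is idempotent.
#'
#' @param corr a \linkS4class{CorrelationEstimate} or symmetric matrix with
#'   unit diagonal.
#' @param tolerance smallest admissible eigenvalue (default 1e-8).
#' @return a \linkS4class{CorrelationEstimate} with \code{psdRepaired} set
#'   iff the matrix changed.
#' @export
nearestPSD <- function(corr, tolerance = 1e-8) {
  if (is.matrix(corr)) {
    corr <- methods::new("CorrelationEstimate", matrix = corr,
                         nEffective = 0L, method = "spearman",
                         psdRepaired = FALSE,
                         minEigenvalueBefore = NA_real_)
  }
  res <- cpp_psd_clip(corr@matrix, tolerance)
  M <- res$matrix
  dimnames(M) <- dimnames(corr@matrix)
  methods::new("CorrelationEstimate", matrix = M,
               nEffective = corr@nEffective, method = corr@method,
               psdRepaired = corr@psdRepaired || isTRUE(res$changed),
               minEigenvalueBefore = res$min_eig_before)
}

setMethod("show", "CorrelationEstimate", function(object) {
  cat(sprintf("CorrelationEstimate (%s): %d variables, n = %d%s\n",
              object@method, ncol(object@matrix), object@nEffective,
              if (object@psdRepaired) ", PSD-repaired" else ""))
})

#' Write / read a correlation matrix as CSV
#' @param corr a \linkS4class{CorrelationEstimate} or matrix.
#' @param file path to a CSV file with header row and row-name column.
#' @return \code{readCorrelationCSV} returns a numeric matrix.
#' @export
writeCorrelationCSV <- function(corr, file) {
  M <- if (is(corr, "CorrelationEstimate")) corr@matrix else corr
  write.csv(M, file, row.names = TRUE)
  invisible(file)
}

#' @rdname writeCorrelationCSV
#' @export
readCorrelationCSV <- function(file) {
  d <- read.csv(file, row.names = 1, check.names = FALSE)
  as.matrix(d)
}
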