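#' @include cytonet-package.R
NULL

.ROLES  <- c("cytokine", "symptom", "covariate", "treatment", "severity",
             "screening")
.SCALES <- c("continuous", "ordinal", "binary")

# ---------------------------------------------------------------- synth -----

#' Ground-truth network specification
#'
#' Holds a planted symmetric positive-definite precision matrix together with
#' the partial correlations it implies (\eqn{\rho_{ij} =
#' -\Theta_{ij}/\sqrt{\Theta_{ii}\Theta_{jj}}}, zero diagonal by convention).
#' Used as the generating truth for synthetic cohorts and for estimator
#' recovery tests.
#'
#' @slot nVars number of variables.
#' @slot precision symmetric positive-definite precision matrix.
#' @slot truePartials implied partial correlations, zero diagonal.
#' @slot topology one of \code{"empty"}, \code{"chain"}, \code{"hub"},
#'   \code{"block"}, \code{"custom"}.
#' @slot blockAssignment integer block label per variable (may be empty).
#' @slot shrink off-diagonal shrink factor applied to reach positive
#'   definiteness (1 when no repair was needed).
#' @export
setClass("TrueNetworkSpec",
  representation(nVars = "integer", precision = "matrix",
                 truePartials = "matrix", topology = "character",
                 blockAssignment = "integer", shrink = "numeric"))

setValidity("TrueNetworkSpec", function(object) {
  P <- object@precision
  msg <- character()
  if (!isTRUE(all.equal(P, t(P), tolerance = 1e-10)))
    msg <- c(msg, "precision matrix must be symmetric")
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) msg <- c(msg, "precision matrix must be positive definite")
  d <- sqrt(diag(P))
  expected <- -P / outer(d, d)
  diag(expected) <- 0
  if (max(abs(expected - object@truePartials)) > 1e-8)
    msg <- c(msg, "truePartials must equal -precision[i,j]/sqrt(precision[i,i]*precision[j,j])")
  off <- object@truePartials[upper.tri(object@truePartials)]
  if (length(off) && max(abs(off)) >= 1)
    msg <- c(msg, "all true partial correlations must have magnitude < 1")
  if (length(msg)) msg else TRUE
})

#' Marginal distribution specification for one synthetic variable
#'
#' Describes how a latent standard-normal score is mapped to the observed
#' scale: a strictly monotone transform for skewed continuous variables
#' (lognormal-like by default), ordinal-probit thresholding for Likert items,
#' or a single threshold for binary variables.
#'
#' @slot family \code{"skewed_continuous"}, \code{"ordinal"} or
#'   \code{"binary"}.
#' @slot params family-specific parameter list; see the constructors
#'   \code{\link{marginalSkewed}}, \code{\link{marginalOrdinal}},
#'   \code{\link{marginalBinary}}.
#' @export
setClass("MarginalSpec",
  representation(family = "character", params = "list"))

setValidity("MarginalSpec", function(object) {
  fam <- object@family
  p <- object@params
  if (!fam %in% c("skewed_continuous", "ordinal", "binary"))
    return("family must be skewed_continuous, ordinal or binary")
  if (fam == "ordinal") {
    th <- p$thresholds
    if (length(th) < 1L || any(diff(th) <= 0))
      return("ordinal thresholds must be strictly increasing (>= 1 threshold)")
    if (length(th) + 1L < 2L) return("ordinal marginals need >= 2 categories")
  }
  if (fam == "skewed_continuous") {
    grid <- seq(-6, 6, by = 0.05)
    vals <- applyMarginal(object, grid)
    if (any(diff(vals) <= 0))
      return("skewed_continuous transform must be strictly increasing")
  }
  TRUE
})

#' Two-arm synthetic cohort specification
#'
#' Arm A is generated from \code{networkA}; arm B from the same precision
#' matrix with off-diagonals scaled by \code{attenuation} (a convex
#' combination with the diagonal, so positive definiteness is preserved).
#'
#' @slot nPerArm integer vector of length 2 (arm A, arm B sizes).
#' @slot networkA generating \linkS4class{TrueNetworkSpec} for arm A.
#' @slot attenuation factor in [0, 1] applied to arm-B precision
#'   off-diagonals; 1 = identical arms, 0 = empty arm-B network.
#' @slot marginals list of \linkS4class{MarginalSpec}, one per variable.
#' @slot varNames,roles,scales,instruments per-variable metadata used when
#'   materialising a \linkS4class{CohortTable}.
#' @slot pairedCoupling latent correlation between a subject's repeated
#'   draws when a paired (two-timepoint) design is generated.
#' @slot seed base seed; arms and timepoints use documented offsets.
#' @export
setClass("CohortSpec",
  representation(nPerArm = "integer", networkA = "TrueNetworkSpec",
                 attenuation = "numeric", marginals = "list",
                 varNames = "character", roles = "character",
                 scales = "character", instruments = "character",
                 pairedCoupling = "numeric", seed = "integer"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (length(object@nPerArm) != 2L || any(object@nPerArm < 3L))
    msg <- c(msg, "nPerArm must give two arm sizes, each >= 3")
  if (object@attenuation < 0 || object@attenuation > 1)
    msg <- c(msg, "attenuation must lie in [0, 1]")
  if (length(object@marginals) != object@networkA@nVars)
    msg <- c(msg, "one MarginalSpec per network variable is required")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------- assoc -----

#' Rank-correlation estimate with PSD provenance
#'
#' @slot matrix symmetric Spearman correlation matrix, unit diagonal.
#' @slot nEffective subjects used (minimum pairwise n under the pairwise
#'   missing-data policy).
#' @slot method fixed tag \code{"spearman"}.
#' @slot psdRepaired whether eigenvalue clipping changed the matrix.
#' @slot minEigenvalueBefore smallest eigenvalue before any repair.
#' @export
setClass("CorrelationEstimate",
  representation(matrix = "matrix", nEffective = "integer",
                 method = "character", psdRepaired = "logical",
                 minEigenvalueBefore = "numeric"))

setValidity("CorrelationEstimate", function(object) {
  M <- object@matrix
  msg <- character()
  if (!isTRUE(all.equal(M, t(M), tolerance = 1e-10)))
    msg <- c(msg, "correlation matrix must be symmetric")
  if (any(abs(diag(M) - 1) > 1e-12))
    msg <- c(msg, "correlation matrix must have unit diagonal")
  if (max(abs(M)) > 1 + 1e-12)
    msg <- c(msg, "correlation entries must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

# -------------------------------------------------------------- estimate ----

#' Regularized partial-correlation network
#'
#' @slot weights symmetric matrix of regularized partial correlations, zero
#'   diagonal.
#' @slot nodeNames node labels.
#' @slot selectedLambda EBIC-selected penalty.
#' @slot ebicGamma EBIC sparsity hyperparameter \eqn{\gamma}.
#' @slot pathLambdas,pathEbics,pathEdgeCounts full penalty-path diagnostics.
#' @slot edgeCount number of nonzero upper-triangle weights.
#' @slot n,p subjects and variables used in estimation.
#' @slot precision selected penalized precision matrix.
#' @export
setClass("NetworkModel",
  representation(weights = "matrix", nodeNames = "character",
                 selectedLambda = "numeric", ebicGamma = "numeric",
                 pathLambdas = "numeric", pathEbics = "numeric",
                 pathEdgeCounts = "integer", edgeCount = "integer",
                 n = "integer", p = "integer", precision = "matrix"))

setValidity("NetworkModel", function(object) {
  W <- object@weights
  msg <- character()
  if (!isTRUE(all.equal(W, t(W), tolerance = 1e-10)))
    msg <- c(msg, "weights must be symmetric")
  if (any(abs(diag(W)) > 1e-12))
    msg <- c(msg, "weights must have zero diagonal")
  E <- sum(abs(W[upper.tri(W)]) > 1e-10)
  if (E != object@edgeCount)
    msg <- c(msg, "edgeCount must equal the number of nonzero upper-triangle weights")
  if (length(object@pathEbics)) {
    best <- min(object@pathEbics)
    i <- which(object@pathEbics <= best + 1e-9)[1L]  # ties -> larger lambda
    if (abs(object@pathLambdas[i] - object@selectedLambda) > 1e-12)
      msg <- c(msg, "selectedLambda must attain the path EBIC minimum (ties toward larger lambda)")
  }
  if (length(msg)) msg else TRUE
})

# --------------------------------------------------------------- metrics ----

#' Node strength centrality table
#'
#' @slot table \code{DataFrame} with columns \code{node}, \code{strength},
#'   \code{z}, \code{rank}, \code{degree}, \code{degreeFraction}.
#' @export
setClass("CentralityTable", representation(table = "DFrame"))

# ----------------------------------------------------------- communities ----

#' Spinglass community assignment
#'
#' @slot labels integer community label per node (contiguous from 1).
#' @slot nCommunities number of distinct labels.
#' @slot hamiltonian energy of the labeling under the signed Potts
#'   objective (exactly recomputable from weights and labels).
#' @slot seed RNG seed that produced the assignment.
#' @slot params annealing and resolution parameters.
#' @export
setClass("CommunityAssignment",
  representation(labels = "integer", nCommunities = "integer",
                 hamiltonian = "numeric", seed = "integer", params = "list"))

setValidity("CommunityAssignment", function(object) {
  u <- sort(unique(object@labels))
  if (!identical(u, seq_along(u)))
    return("labels must be contiguous integers starting at 1")
  if (object@nCommunities != length(u))
    return("nCommunities must equal the number of distinct labels")
  TRUE
})

# ------------------------------------------------------------- stability ----

#' Nonparametric edge bootstrap result
#'
#' @slot B requested bootstrap samples; \code{BEffective} completed ones.
#' @slot edges \code{DataFrame} with one row per node pair: endpoints,
#'   observed weight, positive inclusion proportion (weight estimated > 0),
#'   sign-agnostic nonzero proportion, and the reliability flag
#'   (\code{positiveProportion >= 0.5}).
#' @slot weightSamples matrix of bootstrap edge weights (BEffective x edges).
#' @slot settings estimator settings echo.
#' @slot seed RNG seed.
#' @export
setClass("BootstrapResult",
  representation(B = "integer", BEffective = "integer", edges = "DFrame",
                 weightSamples = "matrix", settings = "list",
                 seed = "integer"))

#' Case-dropping stability result (CS-coefficient)
#'
#' @slot dropGrid case-drop proportions examined.
#' @slot correlations matrix (B x levels) of Spearman correlations between
#'   subsample and full-sample strength centralities (NA for skipped levels).
#' @slot csCoefficient largest grid proportion at which at least
#'   \code{certainty} of the correlations are \code{>= corThreshold}
#'   (0 when no level qualifies).
#' @slot corThreshold,certainty the 0.70 / 0.95 stability criterion.
#' @slot settings estimator settings echo.
#' @slot seed RNG seed.
#' @export
setClass("StabilityResult",
  representation(dropGrid = "numeric", correlations = "matrix",
                 csCoefficient = "numeric", corThreshold = "numeric",
                 certainty = "numeric", settings = "list", seed = "integer"))

# --------------------------------------------------------------- compare ----

#' Network comparison test result
#'
#' @slot design \code{"independent"} or \code{"paired"}.
#' @slot SObserved absolute difference in global strength.
#' @slot MObserved maximum absolute edge-weight difference.
#' @slot pS,pM permutation p-values (add-one convention, never exactly 0).
#' @slot nPermutations permutations performed.
#' @slot SNull,MNull permutation null distributions.
#' @slot strengthDiffNull,edgeDiffNull per-node / per-edge permutation
#'   statistics reused by the post-hoc tests.
#' @slot networkA,networkB the two estimated \linkS4class{NetworkModel}s.
#' @slot alpha significance level gating the post-hoc tests.
#' @slot seed RNG seed.
#' @export
setClass("NCTResult",
  representation(design = "character", SObserved = "numeric",
                 MObserved = "numeric", pS = "numeric", pM = "numeric",
                 nPermutations = "integer", SNull = "numeric",
                 MNull = "numeric", strengthDiffNull = "matrix",
                 edgeDiffNull = "matrix", networkA = "NetworkModel",
                 networkB = "NetworkModel", alpha = "numeric",
                 seed = "integer"))

setValidity("NCTResult", function(object) {
  msg <- character()
  if (object@SObserved < 0 || object@MObserved < 0)
    msg <- c(msg, "S and M statistics are absolute differences and must be >= 0")
  for (p in c(object@pS, object@pM))
    if (p <= 0 || p > 1)
      msg <- c(msg, "permutation p-values must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------- cohort ----

#' Subject-by-variable cohort container
#'
#' A \linkS4class{SummarizedExperiment} subclass storing variables as rows
#' (assay \code{"values"}, variables x subjects) with per-variable metadata
#' in \code{rowData} (\code{role}, \code{scale}, \code{instrument}) and
#' subject identifiers as column names. The analysis-facing orientation
#' (subjects x variables) is returned by \code{\link{cohortMatrix}}.
#'
#' @export
setClass("CohortTable", contains = "SummarizedExperiment")

setValidity("CohortTable", function(object) {
  msg <- character()
  rd <- rowData(object)
  if (!all(c("role", "scale") %in% colnames(rd)))
    return("rowData must contain 'role' and 'scale' columns")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "variable names must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "subject ids must be unique")
  if (!all(rd$role %in% .ROLES))
    msg <- c(msg, sprintf("roles must be one of: %s", paste(.ROLES, collapse = ", ")))
  if (!all(rd$scale %in% .SCALES))
    msg <- c(msg, sprintf("scales must be one of: %s", paste(.SCALES, collapse = ", ")))
  tr <- which(rd$role == "treatment")
  if (length(tr) > 1L) msg <- c(msg, "at most one treatment variable is allowed")
  if (length(tr) == 1L) {
    v <- assay(object)[tr, ]
    if (!all(v[!is.na(v)] %in% c(1, 2)))
      msg <- c(msg, "treatment must be coded 1 (placebo) / 2 (active)")
  }
  if (length(msg)) msg else TRUE
})
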