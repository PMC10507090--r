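#' @include AllClasses.R cohort.R
NULL

# ------------------------------------------------------------- marginals ----

#' Marginal specifications for synthetic variables
#'
#' Observed variables are generated by transforming a latent standard-normal
#' score \eqn{z}. Because every transform is strictly monotone, the Spearman
#' correlation of any transformed pair equals that of the latent pair.
#'
#' \code{marginalSkewed} maps \eqn{z \mapsto location + scale \cdot
#' e^{shape \cdot z}} (lognormal-like; skewness > 1 for shape = 1). With
#' \code{shape = 0} the transform degrades to the affine map \eqn{location +
#' scale \cdot z} for symmetric continuous variables such as age.
#' \code{marginalOrdinal} thresholds \eqn{z} at strictly increasing cut
#' points (ordinal-probit convention); category codes start at
#' \code{baseCategory}. \code{marginalBinary} is a single threshold at the
#' normal quantile of \code{1 - prob}.
#'
#' @param location,scale,shape lognormal-like transform parameters
#'   (\code{scale > 0}).
#' @param thresholds strictly increasing latent cut points.
#' @param baseCategory code of the lowest category (0 for CDSS items, 1 for
#'   PANSS items).
#' @param prob probability of the upper (coded 2) category.
#' @param codes the two codes for a binary variable (default 1/2).
#' @return a \linkS4class{MarginalSpec}.
#' @examples
#' m <- marginalOrdinal(thresholds = c(-1, 0, 1))
#' applyMarginal(m, c(-2, -0.5, 0.5, 2))
#' @export
marginalSkewed <- function(location = 0, scale = 1, shape = 1) {
  stopifnot(scale > 0, shape >= 0)
  methods::new("MarginalSpec", family = "skewed_continuous",
               params = list(location = location, scale = scale,
                             shape = shape))
}

#' @rdname marginalSkewed
#' @export
marginalOrdinal <- function(thresholds, baseCategory = 0) {
  methods::new("MarginalSpec", family = "ordinal",
               params = list(thresholds = as.numeric(thresholds),
                             baseCategory = baseCategory))
}

#' @rdname marginalSkewed
#' @export
marginalBinary <- function(prob = 0.5, codes = c(1, 2)) {
  stopifnot(prob > 0, prob < 1, length(codes) == 2L)
  methods::new("MarginalSpec", family = "binary",
               params = list(prob = prob, codes = codes))
}

#' Calibrate a skewed marginal to a target mean and SD
#'
#' Solves the lognormal moment equations so the generated variable has the
#' requested positive mean and standard deviation exactly (location fixed at
#' 0): \eqn{shape^2 = \log(1 + cv^2)}, \eqn{scale = mean \cdot
#' e^{-shape^2/2}}.
#'
#' @param mean,sd target moments (\code{mean > 0}).
#' @return a \linkS4class{MarginalSpec}.
#' @export
marginalFromMoments <- function(mean, sd) {
  stopifnot(mean > 0, sd > 0)
  s2 <- log(1 + (sd / mean)^2)
  marginalSkewed(location = 0, scale = mean * exp(-s2 / 2),
                 shape = sqrt(s2))
}

#' Apply a marginal transform to latent normal scores
#' @param m a \linkS4class{MarginalSpec}.
#' @param z numeric latent scores.
#' @return transformed values on the observed scale.
#' @export
applyMarginal <- function(m, z) {
  p <- m@params
  switch(m@family,
    skewed_continuous = {
      if (!is.null(p$transform)) p$transform(z)
      else if (p$shape == 0) p$location + p$scale * z
      else p$location + p$scale * exp(p$shape * z)
    },
    ordinal = p$baseCategory + findInterval(z, p$thresholds),
    binary = p$codes[1L + (z > qnorm(1 - p$prob))])
}

# ---------------------------------------------------------- true networks ---

.partials_of <- function(P) {
  d <- sqrt(diag(P))
  R <- -P / outer(d, d)
  diag(R) <- 0
  R
}

# uniform off-diagonal shrink toward the diagonal until positive definite;
# bisection to 1e-10 on the smallest eigenvalue
.pd_repair <- function(P, floor = 1e-3) {
  mineig <- function(a) {
    M <- a * P + (1 - a) * diag(diag(P))
    min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  }
  if (mineig(1) > 1e-10) return(list(precision = P, shrink = 1))
  if (mineig(floor) <= 0)
    stop(sprintf(
      "cannot reach positive definiteness: off-diagonal magnitude %.3f is infeasible even at the shrink floor %.3f",
      max(abs(P[upper.tri(P)])), floor))
  lo <- floor; hi <- 1
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (mineig(mid) > 1e-10) lo <- mid else hi <- mid
  }
  a <- lo
  list(precision = a * P + (1 - a) * diag(diag(P)), shrink = a)
}

#' Build a ground-truth sparse network
#'
#' Constructs a precision matrix with unit diagonal and the requested edge
#' pattern, repairs it to positive definiteness if needed by uniformly
#' shrinking the off-diagonals toward the diagonal (the applied factor is
#' recorded in the \code{shrink} slot), and derives the implied partial
#' correlations. Note the sign convention: an off-diagonal precision entry
#' \eqn{\theta} yields a partial correlation of \eqn{-\theta}.
#'
#' @param topology \code{"empty"}, \code{"chain"} (edges i, i+1),
#'   \code{"hub"} (node 1 linked to all others), \code{"block"}
#'   (within-block edges only) or \code{"custom"} (pattern from
#'   \code{pattern}).
#' @param nVars number of variables (>= 2).
#' @param edgeValue signed off-diagonal precision value at pattern edges
#'   (default -0.3, giving positive partial correlations of 0.3 before any
#'   repair).
#' @param nBlocks number of equal blocks for the block topology.
#' @param pattern logical or numeric symmetric matrix for the custom
#'   topology (nonzero entries become edges at \code{edgeValue}, or their
#'   own value if \code{pattern} is numeric).
#' @return a \linkS4class{TrueNetworkSpec}.
#' @examples
#' spec <- buildTrueNetwork("chain", 3, edgeValue = -0.5)
#' truePartials(spec)[1, 2]  # 0.5
#' @export
buildTrueNetwork <- function(topology = c("empty", "chain", "hub", "block",
                                          "custom"),
                             nVars, edgeValue = -0.3, nBlocks = 2,
                             pattern = NULL) {
  topology <- match.arg(topology)
  stopifnot(nVars >= 2)
  p <- as.integer(nVars)
  P <- diag(p)
  blocks <- integer(0)
  if (topology == "chain") {
    for (i in seq_len(p - 1)) P[i, i + 1] <- P[i + 1, i] <- edgeValue
  } else if (topology == "hub") {
    for (i in 2:p) P[1, i] <- P[i, 1] <- edgeValue
  } else if (topology == "block") {
    blocks <- as.integer(cut(seq_len(p), nBlocks, labels = FALSE))
    for (i in seq_len(p - 1)) for (j in (i + 1):p)
      if (blocks[i] == blocks[j]) P[i, j] <- P[j, i] <- edgeValue
  } else if (topology == "custom") {
    if (is.null(pattern)) stop("custom topology requires a pattern matrix")
    M <- as.matrix(pattern)
    stopifnot(nrow(M) == p, ncol(M) == p)
    if (is.logical(pattern) || all(M %in% c(0, 1))) M <- M * edgeValue
    M <- (M + t(M)) / 2
    diag(M) <- 0
    P <- diag(p) + M
  }
  rep <- .pd_repair(P)
  methods::new("TrueNetworkSpec", nVars = p, precision = rep$precision,
               truePartials = .partials_of(rep$precision),
               topology = topology, blockAssignment = blocks,
               shrink = rep$shrink)
}

#' @rdname accessors
#' @export
setMethod("truePartials", "TrueNetworkSpec", function(x) x@truePartials)

#' @rdname accessors
#' @export
setMethod("precisionMatrix", "TrueNetworkSpec", function(x) x@precision)

setMethod("show", "TrueNetworkSpec", function(object) {
  E <- sum(abs(object@truePartials[upper.tri(object@truePartials)]) > 1e-12)
  cat(sprintf("TrueNetworkSpec: %s topology, %d variables, %d edges",
              object@topology, object@nVars, E))
  if (object@shrink < 1)
    cat(sprintf(" (off-diagonals shrunk by %.4f for positive definiteness)",
                object@shrink))
  cat("\n")
})

# ------------------------------------------------------------- sampling -----

# latent correlation is the standardized inverse of the precision matrix, so
# the planted partial correlations are exact population quantities
.latent_correlation <- function(P) {
  S <- solve(P)
  d <- sqrt(diag(S))
  S / outer(d, d)
}

.sample_latent <- function(Sigma, n) {
  L <- chol(Sigma)
  matrix(rnorm(n * ncol(Sigma)), n) %*% L
}

#' Sample a synthetic cohort from a ground-truth network
#'
#' Draws latent multivariate-normal scores whose correlation matrix is the
#' standardized inverse of the planted precision matrix, then pushes each
#' column through its marginal transform. Identical seeds reproduce
#' identical cohorts.
#'
#' @param spec a \linkS4class{TrueNetworkSpec}.
#' @param marginals list of \linkS4class{MarginalSpec}, one per variable
#'   (a single spec is recycled).
#' @param n subjects (>= 3).
#' @param seed integer seed.
#' @param varNames,roles,scales,instruments optional variable metadata for
#'   the returned \linkS4class{CohortTable}.
#' @param latent optional pre-drawn latent matrix (used internally for
#'   paired designs); when supplied, \code{n} and \code{seed} are ignored.
#' @return a \linkS4class{CohortTable}.
#' @export
sampleCohort <- function(spec, marginals, n, seed = 1L, varNames = NULL,
                         roles = NULL, scales = NULL, instruments = NULL,
                         latent = NULL) {
  p <- spec@nVars
  if (is(marginals, "MarginalSpec")) marginals <- list(marginals)
  if (length(marginals) == 1L) marginals <- rep(marginals, p)
  if (length(marginals) != p)
    stop("need one MarginalSpec per variable")
  if (is.null(latent)) {
    if (n < 3) stop("need at least 3 subjects")
    set.seed(as.integer(seed))
    latent <- .sample_latent(.latent_correlation(spec@precision), n)
  }
  X <- vapply(seq_len(p),
              function(j) as.numeric(applyMarginal(marginals[[j]],
                                                   latent[, j])),
              numeric(nrow(latent)))
  if (is.null(varNames)) varNames <- paste0("V", seq_len(p))
  colnames(X) <- varNames
  if (is.null(roles)) roles <- rep("cytokine", p)
  if (is.null(scales))
    scales <- vapply(marginals, function(m)
      switch(m@family, skewed_continuous = "continuous", ordinal = "ordinal",
             binary = "binary"), character(1))
  CohortTable(X, roles = roles, scales = scales, instruments = instruments)
}

# arm-B precision: off-diagonals scaled by the attenuation factor (a convex
# combination with the diagonal, so positive definiteness is preserved);
# the PD repair is still run defensively for custom inputs
.attenuate <- function(spec, a) {
  P <- a * spec@precision + (1 - a) * diag(diag(spec@precision))
  rep <- .pd_repair(P)
  methods::new("TrueNetworkSpec", nVars = spec@nVars,
               precision = rep$precision,
               truePartials = .partials_of(rep$precision),
               topology = "custom", blockAssignment = spec@blockAssignment,
               shrink = rep$shrink)
}

#' Two-arm cohort specification
#'
#' @param nPerArm arm sizes (length 2).
#' @param networkA generating \linkS4class{TrueNetworkSpec}.
#' @param attenuation arm-B edge attenuation in [0, 1].
#' @param marginals list of \linkS4class{MarginalSpec} (recycled if length
#'   1).
#' @param varNames,roles,scales,instruments variable metadata.
#' @param pairedCoupling latent correlation between repeated draws of one
#'   subject in paired designs (0 = independent timepoints).
#' @param seed base integer seed.
#' @return a \linkS4class{CohortSpec}.
#' @export
cohortSpec <- function(nPerArm, networkA, attenuation = 1, marginals,
                       varNames = NULL, roles = NULL, scales = NULL,
                       instruments = NULL, pairedCoupling = 0.5, seed = 1L) {
  p <- networkA@nVars
  if (is(marginals, "MarginalSpec")) marginals <- list(marginals)
  if (length(marginals) == 1L) marginals <- rep(marginals, p)
  if (is.null(varNames)) varNames <- paste0("V", seq_len(p))
  if (is.null(roles)) roles <- rep("cytokine", p)
  if (is.null(scales))
    scales <- vapply(marginals, function(m)
      switch(m@family, skewed_continuous = "continuous", ordinal = "ordinal",
             binary = "binary"), character(1))
  if (is.null(instruments)) instruments <- rep(NA_character_, p)
  methods::new("CohortSpec", nPerArm = as.integer(nPerArm),
               networkA = networkA, attenuation = attenuation,
               marginals = marginals, varNames = varNames, roles = roles,
               scales = scales, instruments = instruments,
               pairedCoupling = pairedCoupling, seed = as.integer(seed))
}

#' Generate a two-arm synthetic cohort with known ground truth
#'
#' Arm A is drawn from the specification's generating network; arm B from
#' the attenuated network. The base seed expands to per-arm substreams by a
#' fixed counter scheme (arm A uses \code{seed + 1}, arm B \code{seed + 2};
#' paired 6-month draws add 10 to the arm seed).
#'
#' @param spec a \linkS4class{CohortSpec}.
#' @param paired when \code{TRUE}, also generate a second timepoint per arm
#'   whose latent scores correlate \code{pairedCoupling} with the first.
#' @return list with \code{armA}, \code{armB} (\linkS4class{CohortTable}s;
#'   plus \code{armA2}, \code{armB2} when \code{paired}), \code{truthA},
#'   \code{truthB} (\linkS4class{TrueNetworkSpec}s) and
#'   \code{trueGlobalStrength} (named vector for both true partial
#'   networks).
#' @export
makeTwoGroupCohort <- function(spec, paired = FALSE) {
  validObject(spec)
  truthA <- spec@networkA
  truthB <- .attenuate(truthA, spec@attenuation)
  draw <- function(truth, n, seed) {
    set.seed(as.integer(seed))
    Sigma <- .latent_correlation(truth@precision)
    Z1 <- .sample_latent(Sigma, n)
    out <- list(Z1)
    if (paired) {
      rho <- spec@pairedCoupling
      set.seed(as.integer(seed) + 10L)
      E <- .sample_latent(Sigma, n)
      out <- c(out, list(rho * Z1 + sqrt(1 - rho^2) * E))
    }
    out
  }
  mk <- function(latent)
    sampleCohort(truthA, spec@marginals, n = nrow(latent),
                 varNames = spec@varNames, roles = spec@roles,
                 scales = spec@scales, instruments = spec@instruments,
                 latent = latent)
  zA <- draw(truthA, spec@nPerArm[1], spec@seed + 1L)
  zB <- draw(truthB, spec@nPerArm[2], spec@seed + 2L)
  out <- list(armA = mk(zA[[1]]), armB = mk(zB[[1]]),
              truthA = truthA, truthB = truthB,
              trueGlobalStrength = c(armA = globalStrength(truthA),
                                     armB = globalStrength(truthB)))
  if (paired) {
    out$armA2 <- mk(zA[[2]])
    out$armB2 <- mk(zB[[2]])
  }
  out
}
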