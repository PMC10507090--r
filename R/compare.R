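#' @include AllGenerics.R estimate.R metrics.R
NULL

.perm_p <- function(null, obs) (1 + sum(null >= obs)) / (1 + length(null))

#' Permutation-based network comparison test
#'
#' Compares two networks estimated with identical settings: the global
#' strength test statistic S is the absolute difference in the sum of
#' absolute edge weights, and the invariance statistic M is the maximum
#' absolute edge-weight difference. The null distribution is built by
#' re-estimating both networks for randomly regrouped subjects — pooled
#' label permutations preserving group sizes for the independent design, or
#' per-subject condition swaps for the paired (e.g. baseline versus
#' follow-up) design. Two-tailed p-values use the add-one convention
#' \eqn{(1 + \#\{perm \ge obs\})/(1 + nPermutations)} and are therefore
#' never exactly zero. Per-node strength differences and per-edge weight
#' differences are recorded from the same permutation stream for the
#' post-hoc tests.
#'
#' @param dataA,dataB \linkS4class{CohortTable}s or subjects-by-variables
#'   matrices with identical variable sets in identical order; the paired
#'   design additionally requires equal sizes with rows aligned by subject.
#' @param nPermutations permutations (>= 1; 1000 in the reference
#'   protocol).
#' @param design \code{"independent"} or \code{"paired"}.
#' @param gamma,nLambda,minRatio estimator settings shared by every fit.
#' @param alpha significance level gating the post-hoc tests.
#' @param seed integer RNG seed.
#' @return an \linkS4class{NCTResult}.
#' @export
nct <- function(dataA, dataB, nPermutations = 1000,
                design = c("independent", "paired"), gamma = 0,
                nLambda = 100, minRatio = 0.01, alpha = 0.05, seed = 1L) {
  design <- match.arg(design)
  if (nPermutations < 1) stop("nPermutations must be >= 1")
  XA <- if (is(dataA, "CohortTable")) cohortMatrix(dataA) else as.matrix(dataA)
  XB <- if (is(dataB, "CohortTable")) cohortMatrix(dataB) else as.matrix(dataB)
  if (!identical(colnames(XA), colnames(XB)))
    stop("the two tables must share an identical variable set and order")
  XA <- XA[complete.cases(XA), , drop = FALSE]
  XB <- XB[complete.cases(XB), , drop = FALSE]
  if (design == "paired" && nrow(XA) != nrow(XB))
    stop("paired design requires equal group sizes with aligned rows")

  netA <- estimateNetwork(XA, gamma = gamma, nLambda = nLambda,
                          minRatio = minRatio)
  netB <- estimateNetwork(XB, gamma = gamma, nLambda = nLambda,
                          minRatio = minRatio)
  WA <- netA@weights; WB <- netB@weights
  Sobs <- abs(globalStrength(WA) - globalStrength(WB))
  Mobs <- max(abs(WA - WB))

  set.seed(as.integer(seed))
  if (design == "independent") {
    pool <- rbind(XA, XB)
    n <- nrow(pool)
    perm <- vapply(seq_len(nPermutations), function(b) sample.int(n),
                   integer(n))
    null <- cpp_nct_null_independent(pool, nrow(XA), perm, gamma,
                                     as.integer(nLambda), minRatio, 1e-4,
                                     1e-7, 200L, 1e-10)
  } else {
    n <- nrow(XA)
    swap <- matrix(rbinom(n * nPermutations, 1, 0.5), n)
    null <- cpp_nct_null_paired(XA, XB, swap, gamma, as.integer(nLambda),
                                minRatio, 1e-4, 1e-7, 200L, 1e-10)
  }
  methods::new("NCTResult", design = design, SObserved = Sobs,
               MObserved = Mobs,
               pS = .perm_p(null$S_null, Sobs),
               pM = .perm_p(null$M_null, Mobs),
               nPermutations = as.integer(nPermutations),
               SNull = as.numeric(null$S_null),
               MNull = as.numeric(null$M_null),
               strengthDiffNull = null$strength_diff,
               edgeDiffNull = null$edge_diff,
               networkA = netA, networkB = netB, alpha = alpha,
               seed = as.integer(seed))
}

setMethod("show", "NCTResult", function(object) {
  cat(sprintf("NCTResult (%s design, %d permutations)\n", object@design,
              object@nPermutations))
  cat(sprintf("  global strength: %.2f vs %.2f, S = %.2f, p = %.3f\n",
              globalStrength(object@networkA),
              globalStrength(object@networkB), object@SObserved,
              object@pS))
  cat(sprintf("  invariance:      M = %.2f, p = %.3f\n", object@MObserved,
              object@pM))
})

.check_posthoc <- function(res) {
  if (!is(res, "NCTResult"))
    stop("post-hoc tests require a parent NCTResult")
  if (res@pS >= res@alpha && res@pM >= res@alpha)
    warning(sprintf(
      "parent NCT is not significant at alpha = %g (p_S = %.3f, p_M = %.3f); post-hoc tests are exploratory here",
      res@alpha, res@pS, res@pM))
}

#' Post-hoc strength-centrality differences after a significant NCT
#'
#' Per-node statistic \eqn{|s_A(i) - s_B(i)|} with a permutation p-value
#' drawn from the parent test's permutation stream. Both groups' raw
#' strengths and z-scores are reported alongside the difference. Intended
#' to follow a significant NCT; on a non-significant parent a warning is
#' recorded and the table is still returned.
#'
#' @param res an \linkS4class{NCTResult}.
#' @return a \code{DataFrame} with one row per node.
#' @export
posthocStrengthCentrality <- function(res) {
  .check_posthoc(res)
  sA <- rowSums(abs(res@networkA@weights))
  sB <- rowSums(abs(res@networkB@weights))
  zA <- as.data.frame(strengthCentrality(res@networkA))$z
  zB <- as.data.frame(strengthCentrality(res@networkB))$z
  d <- abs(sA - sB)
  pv <- vapply(seq_along(d),
               function(i) .perm_p(res@strengthDiffNull[, i], d[i]),
               numeric(1))
  S4Vectors::DataFrame(node = res@networkA@nodeNames,
                       strengthA = unname(sA), strengthB = unname(sB),
                       zA = zA, zB = zB, difference = unname(d), p = pv)
}

#' Post-hoc edge-invariance differences after a significant NCT
#'
#' Per-edge statistic \eqn{|w_A(i,j) - w_B(i,j)|} with a permutation
#' p-value from the parent stream; Holm adjustment across tested edges by
#' default (\code{"none"} reproduces unadjusted reporting). The tested set
#' can be restricted to pre-specified node pairs.
#'
#' @param res an \linkS4class{NCTResult}.
#' @param adjustment \code{"holm"} (default) or \code{"none"}.
#' @param edges optional two-column matrix or data.frame of node-name pairs
#'   restricting the tested set (default: all pairs).
#' @return a \code{DataFrame} with one row per tested edge.
#' @export
posthocEdgeInvariance <- function(res, adjustment = c("holm", "none"),
                                  edges = NULL) {
  adjustment <- match.arg(adjustment)
  .check_posthoc(res)
  nm <- res@networkA@nodeNames
  ei <- .edge_index(nm)
  WA <- res@networkA@weights; WB <- res@networkB@weights
  d <- abs(WA[cbind(ei$i, ei$j)] - WB[cbind(ei$i, ei$j)])
  keep <- seq_len(nrow(ei))
  if (!is.null(edges)) {
    edges <- as.matrix(edges)
    want <- paste(pmin(edges[, 1], edges[, 2]),
                  pmax(edges[, 1], edges[, 2]))
    havePairs <- paste(pmin(ei$from, ei$to), pmax(ei$from, ei$to))
    keep <- which(havePairs %in% want)
    if (length(keep) == 0L) stop("no requested edge matches the node set")
  }
  pv <- vapply(keep, function(t) .perm_p(res@edgeDiffNull[, t], d[t]),
               numeric(1))
  adj <- if (adjustment == "holm") p.adjust(pv, method = "holm") else pv
  S4Vectors::DataFrame(from = ei$from[keep], to = ei$to[keep],
                       weightA = WA[cbind(ei$i, ei$j)][keep],
                       weightB = WB[cbind(ei$i, ei$j)][keep],
                       difference = d[keep], p = pv, pAdjusted = adj,
                       adjustment = adjustment)
}
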