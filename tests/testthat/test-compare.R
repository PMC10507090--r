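makeArms <- function(n = 120, p = 4, attenuation = 1, seed = 1) {
  tn <- buildTrueNetwork("chain", p, edgeValue = -0.4)
  makeTwoGroupCohort(cohortSpec(c(n, n), tn, attenuation = attenuation,
                                marginals = marginalSkewed(), seed = seed))
}

test_that("identical groups give zero statistics and p-values of 1", {
  tg <- makeArms(seed = 3)
  X <- cohortMatrix(tg$armA)
  r <- nct(X, X, nPermutations = 200, seed = 5)
  expect_equal(r@SObserved, 0)
  expect_equal(r@MObserved, 0)
  expect_equal(r@pS, 1)
  expect_equal(r@pM, 1)
  # post-hoc tables on identical groups: every p is 1 (with a warning that
  # the parent comparison is not significant)
  expect_warning(ph <- posthocStrengthCentrality(r), "not significant")
  expect_true(all(ph$p == 1))
  expect_warning(pe <- posthocEdgeInvariance(r), "not significant")
  expect_true(all(pe$p == 1))
  expect_true(all(pe$pAdjusted == 1))
})

test_that("p-values follow the add-one convention", {
  tg <- makeArms(n = 60, seed = 8)
  r <- nct(cohortMatrix(tg$armA), cohortMatrix(tg$armB),
           nPermutations = 99, seed = 2)
  expect_gte(r@pS, 1 / 100)
  expect_lte(r@pS, 1)
  expect_equal(r@pS, (1 + sum(r@SNull >= r@SObserved)) / 100)
  expect_equal(r@pM, (1 + sum(r@MNull >= r@MObserved)) / 100)
  expect_equal(r@nPermutations, 99L)
})

test_that("swapping the arms leaves the observed statistics unchanged", {
  tg <- makeArms(n = 100, attenuation = 0.5, seed = 13)
  XA <- cohortMatrix(tg$armA); XB <- cohortMatrix(tg$armB)
  r1 <- nct(XA, XB, nPermutations = 300, seed = 4)
  r2 <- nct(XB, XA, nPermutations = 300, seed = 4)
  expect_equal(r1@SObserved, r2@SObserved)
  expect_equal(r1@MObserved, r2@MObserved)
  expect_lt(abs(r1@pS - r2@pS), 0.08)
  expect_lt(abs(r1@pM - r2@pM), 0.08)
})

test_that("input contracts are enforced", {
  tg <- makeArms(n = 30, seed = 6)
  XA <- cohortMatrix(tg$armA); XB <- cohortMatrix(tg$armB)
  expect_error(nct(XA, XB[, c(2, 1, 3, 4)]), "identical variable set")
  expect_error(nct(XA, XB, nPermutations = 0), "nPermutations")
  expect_error(nct(XA, XB[-1, ], design = "paired"), "equal group sizes")
  expect_error(posthocStrengthCentrality(list()), "NCTResult")
})

test_that("paired designs swap per-subject conditions", {
  tg <- makeArms(n = 80, attenuation = 0.3, seed = 10)
  r <- nct(cohortMatrix(tg$armA), cohortMatrix(tg$armB),
           nPermutations = 150, design = "paired", seed = 3)
  expect_equal(r@design, "paired")
  expect_true(r@pS > 0 && r@pS <= 1)
  # determinism under a fixed seed
  r2 <- nct(cohortMatrix(tg$armA), cohortMatrix(tg$armB),
            nPermutations = 150, design = "paired", seed = 3)
  expect_identical(r@SNull, r2@SNull)
})

test_that("a planted single-node attenuation is flagged by the post-hoc tests", {
  # arm B: edges of node 1 zeroed; all other structure shared
  p <- 5
  PA <- diag(p)
  PA[1, 2] <- PA[2, 1] <- -0.45
  PA[3, 4] <- PA[4, 3] <- -0.45
  PB <- PA; PB[1, 2] <- PB[2, 1] <- 0
  tnA <- buildTrueNetwork("custom", p, pattern = PA)
  tnB <- buildTrueNetwork("custom", p, pattern = PB)
  hitsNode <- hitsEdge <- 0
  nrep <- 6
  for (s in seq_len(nrep)) {
    a <- sampleCohort(tnA, marginalSkewed(), n = 500, seed = 300 + s)
    b <- sampleCohort(tnB, marginalSkewed(), n = 500, seed = 600 + s)
    r <- nct(cohortMatrix(a), cohortMatrix(b), nPermutations = 200,
             seed = s)
    ph <- suppressWarnings(posthocStrengthCentrality(r))
    if (which.min(ph$p) %in% c(1, 2)) hitsNode <- hitsNode + 1
    pe <- suppressWarnings(posthocEdgeInvariance(r))
    idx <- which(pe$from == "V1" & pe$to == "V2")
    if (which.min(pe$p) == idx) hitsEdge <- hitsEdge + 1
    expect_true(all(pe$pAdjusted >= pe$p))  # Holm never decreases
  }
  expect_gte(hitsNode, nrep - 1)
  expect_gte(hitsEdge, nrep - 1)
})

test_that("post-hoc tables report both groups' raw strengths", {
  tg <- makeArms(n = 60, attenuation = 0.2, seed = 17)
  r <- nct(cohortMatrix(tg$armA), cohortMatrix(tg$armB),
           nPermutations = 100, seed = 1)
  ph <- suppressWarnings(posthocStrengthCentrality(r))
  expect_true(all(c("strengthA", "strengthB", "zA", "zB") %in% colnames(ph)))
  expect_equal(ph$strengthA,
               unname(rowSums(abs(edgeWeights(r@networkA)))))
  pe <- suppressWarnings(posthocEdgeInvariance(r, adjustment = "none"))
  expect_equal(pe$p, pe$pAdjusted)
  # restricting the tested edge set
  pe2 <- suppressWarnings(
    posthocEdgeInvariance(r, edges = cbind("V1", "V2")))
  expect_equal(nrow(pe2), 1L)
})
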