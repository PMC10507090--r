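test_that("the edge reliability rule uses the at-least-half boundary", {
  expect_true(isReliableEdge(0.81))
  expect_false(isReliableEdge(0.49))
  expect_true(isReliableEdge(0.50))
})

test_that("edge bootstrap tracks planted and null edges", {
  # one strong planted edge: near-certain inclusion
  P <- diag(4); P[1, 2] <- P[2, 1] <- -0.6
  tn <- buildTrueNetwork("custom", 4, pattern = P)
  ct <- sampleCohort(tn, marginalSkewed(), n = 300, seed = 21)
  boot <- edgeBootstrap(ct, B = 100, seed = 5)
  ed <- as.data.frame(edgeTable(boot))
  planted <- ed[ed$from == "V1" & ed$to == "V2", ]
  expect_gte(planted$positiveProportion, 0.95)
  expect_true(planted$reliable)
  expect_equal(boot@BEffective, 100L)

  # inclusion proportions are the per-column positive fractions of the
  # retained weight samples (recomputable from the stored draws)
  expect_equal(ed$positiveProportion,
               unname(colMeans(boot@weightSamples > 0)))

  # null edges under independence rarely survive a cautious fit
  e <- buildTrueNetwork("empty", 4)
  ct0 <- sampleCohort(e, marginalSkewed(), n = 300, seed = 22)
  boot0 <- edgeBootstrap(ct0, B = 100, gamma = 0.5, seed = 6)
  expect_lte(max(as.data.frame(edgeTable(boot0))$positiveProportion), 0.2)
})

test_that("bootstrap results are reproducible from the seed", {
  tn <- buildTrueNetwork("chain", 4, edgeValue = -0.4)
  ct <- sampleCohort(tn, marginalSkewed(), n = 150, seed = 31)
  b1 <- edgeBootstrap(ct, B = 40, seed = 9)
  b2 <- edgeBootstrap(ct, B = 40, seed = 9)
  expect_identical(b1@weightSamples, b2@weightSamples)
  s1 <- caseDroppingStability(ct, B = 20, seed = 9)
  s2 <- caseDroppingStability(ct, B = 20, seed = 9)
  expect_identical(s1@correlations, s2@correlations)
  expect_identical(csCoefficient(s1), csCoefficient(s2))
})

test_that("the CS rule returns grid boundaries correctly", {
  grid <- seq(0.05, 0.75, by = 0.10)
  allPass <- matrix(0.9, 50, length(grid))
  expect_equal(cytonet:::.cs_from_correlations(allPass, grid, 0.70, 0.95),
               0.75)
  nonePass <- matrix(0.3, 50, length(grid))
  expect_equal(cytonet:::.cs_from_correlations(nonePass, grid, 0.70, 0.95),
               0)
  # mixed: high correlations only while dropping few cases
  mixed <- cbind(matrix(0.95, 50, 3), matrix(0.2, 50, 5))
  expect_equal(cytonet:::.cs_from_correlations(mixed, grid, 0.70, 0.95),
               0.25)
  # CS is non-increasing as the correlation threshold rises
  set.seed(2)
  draws <- matrix(runif(50 * 8, 0.4, 1), 50, 8)
  cs <- vapply(seq(0.5, 0.9, by = 0.1), function(thr)
    cytonet:::.cs_from_correlations(draws, grid, thr, 0.95), numeric(1))
  expect_true(all(diff(cs) <= 0))
})

test_that("case-dropping stability skips infeasible levels and scores hubs", {
  tn <- buildTrueNetwork("hub", 12, edgeValue = -0.25)
  ct <- sampleCohort(tn, marginalSkewed(), n = 60, seed = 41)
  # dropping 75% of 60 leaves 15 > p + 1 = 13: fine; but on 20 subjects
  # most levels are infeasible
  ct2 <- sampleCohort(tn, marginalSkewed(), n = 20, seed = 41)
  w <- capture_warnings(caseDroppingStability(ct2, B = 5, seed = 1))
  expect_true(any(grepl("skipped", w)))

  st <- caseDroppingStability(ct, B = 25, seed = 3)
  expect_true(csCoefficient(st) %in% c(0, st@dropGrid))
})

test_that("bootstrap stratifies by arm when a treatment node is present", {
  tn <- buildTrueNetwork("chain", 3, edgeValue = -0.4)
  tg <- makeTwoGroupCohort(cohortSpec(c(40, 60), tn, attenuation = 1,
                                      marginals = marginalSkewed(),
                                      seed = 2))
  X <- rbind(cohortMatrix(tg$armA), cohortMatrix(tg$armB))
  d <- cbind(X, treatment = c(rep(1, 40), rep(2, 60)))
  rownames(d) <- sprintf("S%03d", seq_len(nrow(d)))
  ct <- CohortTable(d, roles = c(rep("cytokine", 3), "treatment"))
  boot <- edgeBootstrap(ct, B = 25, seed = 4)
  expect_equal(boot@BEffective, 25L)
  expect_equal(nrow(edgeTable(boot)), choose(4, 2))
})
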