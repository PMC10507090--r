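test_that("planted topologies realize the requested precision pattern", {
  # independence case
  e <- buildTrueNetwork("empty", 4)
  expect_equal(e@precision, diag(4))
  expect_true(all(truePartials(e) == 0))

  # 3-chain with off-diagonal -0.5: hand-derived partials are +0.5
  ch <- buildTrueNetwork("chain", 3, edgeValue = -0.5)
  expect_equal(ch@precision,
               matrix(c(1, -0.5, 0, -0.5, 1, -0.5, 0, -0.5, 1), 3))
  ev <- eigen(ch@precision, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_equal(truePartials(ch)[1, 2], 0.5)
  expect_equal(truePartials(ch)[1, 3], 0)

  # hub: node 1 carries all edges and the largest true strength
  hb <- buildTrueNetwork("hub", 5, edgeValue = -0.3)
  tp <- truePartials(hb)
  expect_equal(sum(abs(tp[1, ]) > 1e-12), 4)
  for (i in 2:5) expect_equal(sum(abs(tp[i, ]) > 1e-12), 1)
  s <- as.data.frame(strengthCentrality(tp))$strength
  expect_true(all(s[1] > s[-1]))

  # block: edges only within blocks
  bl <- buildTrueNetwork("block", 6, edgeValue = -0.2, nBlocks = 2)
  tp <- truePartials(bl)
  expect_true(all(tp[1:3, 4:6] == 0))
  expect_true(all(tp[1:3, 1:3][upper.tri(diag(3))] > 0))
})

test_that("positive-definiteness repair shrinks and records, or fails loudly", {
  # chain(3) at -0.9 is indefinite (eigenvalue 1 - 0.9*sqrt(2) < 0)
  ch <- buildTrueNetwork("chain", 3, edgeValue = -0.9)
  expect_lt(ch@shrink, 1)
  expect_gt(min(eigen(ch@precision, only.values = TRUE)$values), 0)
  # repair never inflates a partial beyond its pre-repair magnitude
  expect_true(all(abs(truePartials(ch)) <= 0.9 + 1e-12))

  # magnitudes infeasible even at the shrink floor fail with the magnitude
  P <- matrix(-500, 6, 6); diag(P) <- 0
  expect_error(buildTrueNetwork("custom", 6, pattern = P), "infeasible")
})

test_that("sampled cohorts carry the planted rank correlations", {
  # independence: all pairwise Spearman within 0.05 of zero
  e <- buildTrueNetwork("empty", 4)
  ct <- sampleCohort(e, marginalSkewed(), n = 5000, seed = 42)
  C <- rankCorrelationMatrix(ct)@matrix
  expect_lt(max(abs(C[upper.tri(C)])), 0.05)

  # latent Pearson rho = 0.5 under monotone maps: population Spearman is
  # (6/pi) asin(rho/2) = 0.4826
  pair <- buildTrueNetwork("chain", 2, edgeValue = -0.5)
  Sigma <- solve(pair@precision)
  expect_equal(Sigma[1, 2] / sqrt(Sigma[1, 1] * Sigma[2, 2]), 0.5)
  ct2 <- sampleCohort(pair, marginalSkewed(shape = 2), n = 50000, seed = 7)
  r <- rankCorrelationMatrix(ct2)@matrix[1, 2]
  expect_equal(r, (6 / pi) * asin(0.5 / 2), tolerance = 0.021)

  # ordinal thresholds (-1, 0, 1): category masses are Phi differences
  m <- marginalOrdinal(thresholds = c(-1, 0, 1))
  ct3 <- sampleCohort(buildTrueNetwork("empty", 2), list(m, m),
                      n = 50000, seed = 3)
  prop <- tabulate(cohortMatrix(ct3)[, 1] + 1, 4) / 50000
  expect_equal(prop, diff(pnorm(c(-Inf, -1, 0, 1, Inf))), tolerance = 0.01)
})

test_that("monotone transforms leave Spearman correlations invariant", {
  pair <- buildTrueNetwork("chain", 2, edgeValue = -0.4)
  margs <- list(
    list(marginalSkewed(shape = 1), marginalSkewed(shape = 0)),
    list(marginalSkewed(location = 5, scale = 3, shape = 0.5),
         marginalSkewed(shape = 3)))
  for (mg in margs) {
    a <- sampleCohort(pair, mg, n = 50000, seed = 11)
    b <- sampleCohort(pair, list(marginalSkewed(shape = 0),
                                 marginalSkewed(shape = 0)),
                      n = 50000, seed = 11)
    ra <- rankCorrelationMatrix(a)@matrix[1, 2]
    rb <- rankCorrelationMatrix(b)@matrix[1, 2]
    expect_equal(ra, rb, tolerance = 1e-10)  # same latent draw, same ranks
  }
})

test_that("marginal specifications validate their invariants", {
  expect_error(marginalOrdinal(thresholds = c(0, 0, 1)), "increasing")
  expect_error(marginalOrdinal(thresholds = numeric(0)), "increasing")
  expect_error(marginalSkewed(scale = -1))
  expect_silent(marginalBinary(prob = 0.258))
  # a custom non-monotone transform is rejected by the numeric grid check
  expect_error(methods::new(
    "MarginalSpec", family = "skewed_continuous",
    params = list(location = 0, scale = 1, shape = 1,
                  transform = function(z) -z^2)), "monotone|increasing")
})

test_that("identical seeds reproduce identical cohorts", {
  tn <- buildTrueNetwork("hub", 6, edgeValue = -0.25)
  a <- sampleCohort(tn, marginalSkewed(), n = 40, seed = 99)
  b <- sampleCohort(tn, marginalSkewed(), n = 40, seed = 99)
  expect_identical(cohortMatrix(a), cohortMatrix(b))
  expect_error(sampleCohort(tn, marginalSkewed(), n = 2, seed = 1),
               "at least 3")
})

test_that("two-arm generation honours the attenuation contract", {
  tn <- buildTrueNetwork("chain", 3, edgeValue = -0.5)
  spec1 <- cohortSpec(c(20, 20), tn, attenuation = 1,
                      marginals = marginalSkewed(), seed = 5)
  tg1 <- makeTwoGroupCohort(spec1)
  expect_equal(tg1$truthA@precision, tg1$truthB@precision)

  spec0 <- cohortSpec(c(20, 20), tn, attenuation = 0,
                      marginals = marginalSkewed(), seed = 5)
  tg0 <- makeTwoGroupCohort(spec0)
  expect_true(all(truePartials(tg0$truthB) == 0))
  expect_equal(unname(tg0$trueGlobalStrength["armB"]), 0)

  # attenuation 0.5 on chain(3, -0.5): partials exactly halved, no repair
  spec5 <- cohortSpec(c(20, 20), tn, attenuation = 0.5,
                      marginals = marginalSkewed(), seed = 5)
  tg5 <- makeTwoGroupCohort(spec5)
  expect_equal(tg5$truthB@shrink, 1)
  expect_equal(truePartials(tg5$truthB)[1, 2], 0.25)

  # paired draws couple latent scores across timepoints
  tgp <- makeTwoGroupCohort(spec5, paired = TRUE)
  expect_equal(dim(cohortMatrix(tgp$armA2)), dim(cohortMatrix(tgp$armA)))
})
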