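test_that("penalty paths are log-spaced from the largest off-diagonal", {
  # identity correlation: lambda_max floored, path still valid
  path0 <- lambdaPath(diag(4), nLambda = 5)
  expect_equal(path0[1], 1e-4)
  expect_true(all(diff(path0) < 0))

  # max |off-diagonal| 0.6, 3 points, ratio 0.01 -> (0.6, 0.06, 0.006)
  C <- diag(3); C[1, 2] <- C[2, 1] <- 0.6; C[1, 3] <- C[3, 1] <- 0.2
  expect_equal(lambdaPath(C, nLambda = 3, minRatio = 0.01),
               c(0.6, 0.06, 0.006), tolerance = 1e-12)

  expect_error(lambdaPath(C, minRatio = 1.2), "minRatio")
  expect_error(lambdaPath(C, minRatio = 0), "minRatio")
})

test_that("glasso at lambda = 0 equals the direct inverse", {
  set.seed(31)
  for (p in 3:6) {
    C <- cor(matrix(rnorm(200 * p), 200, p))
    fit <- fitGlasso(C, 0)
    expect_lt(max(abs(fit$precision - solve(C))), 1e-6)
  }
})

test_that("glasso at lambda >= lambda_max returns the empty graph exactly", {
  set.seed(32)
  C <- cor(matrix(rnorm(400), 100, 4))
  lmax <- max(abs(C[upper.tri(C)]))
  for (lam in c(lmax, lmax * 1.5)) {
    Th <- fitGlasso(C, lam)$precision
    off <- Th[upper.tri(Th)]
    expect_identical(unname(off), rep(0, length(off)))
  }
})

test_that("two-variable glasso matches the closed-form soft threshold", {
  # p = 2, rho = 0.5, lambda = 0.2: implied covariance off-diagonal is
  # sign(rho)(|rho| - lambda) = 0.3; precision by direct 2x2 inversion
  C <- matrix(c(1, 0.5, 0.5, 1), 2)
  fit <- fitGlasso(C, 0.2)
  expect_equal(fit$covariance[1, 2], 0.3, tolerance = 1e-7)
  expect_equal(fit$precision, solve(matrix(c(1, 0.3, 0.3, 1), 2)),
               tolerance = 1e-6)
})

test_that("EBIC scoring follows its closed formula", {
  # bare arithmetic: l = -100, E = 3, n = 194, p = 12, gamma = 0.5
  expect_equal(ebicFromComponents(-100, 3, 194, 12, 0.5),
               200 + 3 * log(194) + 6 * log(12))
  expect_equal(ebicFromComponents(-100, 3, 194, 12, 0.5), 230.713,
               tolerance = 1e-3)
  # gamma = 0 reduces to the BIC; E = 0 removes the penalty entirely
  expect_equal(ebicFromComponents(-50, 4, 100, 6, 0), 100 + 4 * log(100))
  expect_equal(ebicFromComponents(-50, 0, 100, 6, 0.5), 100)

  # matrix route agrees with an eigenvalue oracle
  set.seed(9)
  C <- cor(matrix(rnorm(300), 100, 3))
  Th <- fitGlasso(C, 0.1)$precision
  E <- sum(abs(Th[upper.tri(Th)]) > 1e-10)
  ll <- (100 / 2) * (determinant(Th)$modulus[1] - sum(C * Th))
  expect_equal(ebicScore(Th, C, 100, 0.5),
               -2 * ll + E * log(100) + 4 * E * 0.5 * log(3))
  # EBIC penalty is strictly increasing in E at fixed likelihood
  expect_gt(ebicFromComponents(-10, 5, 50, 8, 0.5),
            ebicFromComponents(-10, 4, 50, 8, 0.5))
  # non-PD precision has no log-determinant
  expect_error(ebicScore(diag(c(1, -1)), diag(2), 50, 0), "positive definite")
})

test_that("full estimation finds the chain's edges and rejects degenerate input", {
  tn <- buildTrueNetwork("chain", 3, edgeValue = -0.5)
  ct <- sampleCohort(tn, marginalSkewed(), n = 2000, seed = 12)
  net <- estimateNetwork(ct)
  W <- edgeWeights(net)
  # both true edges are recovered near their planted values; any extra
  # edge is a small EBIC-path false positive, removable by the optional
  # support threshold
  expect_true(abs(W[1, 2]) > 0.3 && abs(W[2, 3]) > 0.3)
  expect_lt(abs(W[1, 3]), 0.05)
  expect_true(validObject(net))
  Wt <- edgeWeights(estimateNetwork(ct, threshold = TRUE))
  expect_equal(Wt[1, 3], 0)
  expect_true(abs(Wt[1, 2]) > 0.3)

  X <- cohortMatrix(ct)
  X[, 2] <- 1
  colnames(X)[2] <- "flatline"
  expect_error(estimateNetwork(X), "constant column.*flatline")
})

test_that("larger EBIC gamma never selects a denser model", {
  tn <- buildTrueNetwork("hub", 8, edgeValue = -0.2)
  for (s in c(3, 14)) {
    ct <- sampleCohort(tn, marginalSkewed(), n = 300, seed = s)
    e0 <- estimateNetwork(ct, gamma = 0)@edgeCount
    e5 <- estimateNetwork(ct, gamma = 0.5)@edgeCount
    expect_lte(e5, e0)
  }
})

test_that("network models serialize to edge list, CSV, GraphML and JSON", {
  tn <- buildTrueNetwork("chain", 4, edgeValue = -0.4)
  ct <- sampleCohort(tn, marginalSkewed(), n = 500, seed = 2)
  net <- estimateNetwork(ct)
  d <- tempfile(); dir.create(d)
  writeNetworkCSV(net, file.path(d, "w.csv"))
  writeEdgeListTSV(net, file.path(d, "e.tsv"))
  writeNetworkGraphML(net, file.path(d, "g.graphml"))
  networkPathJSON(net, file.path(d, "p.json"))
  expect_true(all(file.exists(file.path(d, c("w.csv", "e.tsv", "g.graphml",
                                             "p.json")))))
  el <- read.delim(file.path(d, "e.tsv"))
  expect_equal(nrow(el), net@edgeCount)
  g <- igraph::read_graph(file.path(d, "g.graphml"), format = "graphml")
  expect_equal(igraph::ecount(g), net@edgeCount)
  js <- jsonlite::read_json(file.path(d, "p.json"))
  expect_equal(js$edge_count, net@edgeCount)
})
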