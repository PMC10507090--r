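test_that("Spearman correlations match the rank formula", {
  # perfect inverse ranks
  M <- rankCorrelationMatrix(cbind(x = 1:4, y = 4:1))@matrix
  expect_equal(M["x", "y"], -1)
  expect_equal(diag(M), c(x = 1, y = 1))
  # 1 - 6*sum(d^2)/(n(n^2-1)) with sum(d^2) = 2
  M2 <- rankCorrelationMatrix(cbind(x = c(1, 2, 3), y = c(2, 1, 3)))@matrix
  expect_equal(M2["x", "y"], 0.5)
})

test_that("Spearman equals Pearson on mid-ranked data, with ties", {
  set.seed(20)
  for (rep in 1:5) {
    X <- cbind(rpois(30, 3), rlnorm(30), sample(0:3, 30, TRUE))
    M <- rankCorrelationMatrix(X)@matrix
    oracle <- cor(apply(X, 2, rank))  # average ranks, Pearson
    expect_equal(unname(M), unname(oracle), tolerance = 1e-12)
  }
})

test_that("row order does not affect the correlation matrix", {
  set.seed(4)
  X <- matrix(rnorm(60), 20, 3)
  M1 <- rankCorrelationMatrix(X)@matrix
  M2 <- rankCorrelationMatrix(X[sample(20), ])@matrix
  expect_equal(M1, M2, tolerance = 1e-12)
})

test_that("degenerate inputs fail with informative messages", {
  X <- cbind(a = c(1, 1, 1, 1), b = rnorm(4))
  expect_error(rankCorrelationMatrix(X), "constant column.*a")
  expect_error(rankCorrelationMatrix(matrix(rnorm(4), 2, 2)),
               "fewer than 3")
})

test_that("pairwise policy records the minimum pairwise n", {
  set.seed(8)
  X <- matrix(rnorm(100), 25, 4)
  colnames(X) <- paste0("v", 1:4)
  X[1:6, 1] <- NA
  X[5:10, 2] <- NA
  ce <- rankCorrelationMatrix(X, missingPolicy = "pairwise")
  # v1/v2 share only rows 11..25 plus rows 1:4 of neither... count directly
  nPair <- sum(!is.na(X[, 1]) & !is.na(X[, 2]))
  expect_equal(ce@nEffective, nPair)
  ceC <- rankCorrelationMatrix(X, missingPolicy = "complete_rows")
  expect_equal(ceC@nEffective, sum(complete.cases(X)))
})

test_that("PSD repair clips, renormalizes and is idempotent", {
  # PSD input passes through untouched
  ok <- rankCorrelationMatrix(matrix(rnorm(90), 30, 3))
  rep1 <- nearestPSD(ok)
  expect_false(rep1@psdRepaired)
  expect_identical(rep1@matrix, ok@matrix)

  # the classic indefinite example (determinant < 0)
  bad <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3)
  expect_lt(det(bad), 0)
  fixed <- nearestPSD(bad)
  expect_true(fixed@psdRepaired)
  ev <- eigen(fixed@matrix, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
  expect_equal(diag(fixed@matrix), rep(1, 3))
  # eigenvalue-clipping oracle: clip at 0 and renormalize
  eg <- eigen(bad, symmetric = TRUE)
  A <- eg$vectors %*% diag(pmax(eg$values, 0)) %*% t(eg$vectors)
  oracle <- A / sqrt(outer(diag(A), diag(A)))
  expect_equal(unname(fixed@matrix), unname(oracle), tolerance = 1e-10)

  # idempotence: a second pass changes nothing
  twice <- nearestPSD(fixed)
  expect_false(max(abs(twice@matrix - fixed@matrix)) > 1e-12)
})

test_that("correlation matrices round-trip through CSV", {
  ce <- rankCorrelationMatrix(matrix(rnorm(60), 20, 3,
                                     dimnames = list(NULL, c("a", "b", "c"))))
  f <- tempfile(fileext = ".csv")
  writeCorrelationCSV(ce, f)
  back <- readCorrelationCSV(f)
  expect_equal(back, ce@matrix, tolerance = 1e-12)
})
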