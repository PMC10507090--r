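test_that("global strength sums absolute upper-triangle weights", {
  expect_equal(globalStrength(matrix(0, 4, 4)), 0)
  W <- weightMatrix(3, list(list(1, 2, 0.26), list(1, 3, -0.18),
                            list(2, 3, 0.44)))
  expect_equal(globalStrength(W), 0.88)
  # isolated nodes contribute nothing
  W2 <- rbind(cbind(W, 0), 0)
  expect_equal(globalStrength(W2), 0.88)
})

test_that("strength centrality sums incident absolute weights", {
  # star: centre 3 edges of +0.2
  star <- weightMatrix(4, list(list(1, 2, 0.2), list(1, 3, 0.2),
                               list(1, 4, 0.2)))
  tab <- as.data.frame(strengthCentrality(star))
  expect_equal(tab$strength, c(0.6, 0.2, 0.2, 0.2))
  expect_equal(tab$rank[1], 1L)
  # twice the global strength equals the sum of all node strengths (exact)
  expect_equal(sum(tab$strength), 2 * globalStrength(star))

  # isolated node has zero strength; z-scores standardized
  W <- weightMatrix(3, list(list(1, 2, 0.5)))
  tab2 <- as.data.frame(strengthCentrality(W))
  expect_equal(tab2$strength[3], 0)
  expect_equal(mean(tab2$z), 0)
  expect_equal(sd(tab2$z), 1)

  # all-equal strengths: z-scores all zero by convention
  ring <- weightMatrix(3, list(list(1, 2, 0.3), list(2, 3, 0.3),
                               list(1, 3, 0.3)))
  expect_true(all(as.data.frame(strengthCentrality(ring))$z == 0))
})

test_that("strength centrality is equivariant under node relabeling", {
  set.seed(5)
  tn <- buildTrueNetwork("hub", 6, edgeValue = -0.2)
  W <- truePartials(tn)
  dimnames(W) <- list(letters[1:6], letters[1:6])
  perm <- sample(6)
  a <- as.data.frame(strengthCentrality(W))
  b <- as.data.frame(strengthCentrality(W[perm, perm]))
  expect_equal(b$strength[match(a$node, b$node)], a$strength)
})

test_that("degree fraction reports partners per possible partner", {
  W <- weightMatrix(12, lapply(2:8, function(j) list(1, j, 0.1)))
  expect_equal(degreeFraction(W, 1), 63.6)     # 7 of 11
  expect_equal(degreeFraction(matrix(0, 5, 5), 2), 0)
  full <- matrix(0.2, 5, 5); diag(full) <- 0
  expect_equal(degreeFraction(full, 3), 100)
})

test_that("influential-node selection implements both published rules", {
  # three clear leaders above a 1.0 z threshold, all others far below
  tbl <- centralityWithZ(c(1.23, 1.20, 1.15, 0.3, 0.2, 0.1, 0.05))
  sel <- selectInfluential(tbl, rule = "z_threshold", param = 1.0)
  expect_setequal(sel$nodes, c("N1", "N2", "N3"))
  # the same leaders sit above the largest gap
  selG <- selectInfluential(tbl, rule = "top_gap")
  expect_setequal(selG$nodes, c("N1", "N2", "N3"))

  # all-equal z: no gap to cut at; threshold 0 selects everything
  flat <- centralityWithZ(rep(0, 4))
  expect_warning(s0 <- selectInfluential(flat, rule = "top_gap"), "empty")
  expect_length(s0$nodes, 0)
  expect_length(selectInfluential(flat, rule = "z_threshold", param = 0)$nodes,
                4)
})

test_that("a planted hub is selected by both rules at large n", {
  hits <- c(z_threshold = 0, top_gap = 0)
  nrep <- 8
  tn <- buildTrueNetwork("hub", 12, edgeValue = -0.25)
  for (s in seq_len(nrep)) {
    ct <- sampleCohort(tn, marginalSkewed(), n = 2000, seed = 100 + s)
    cent <- strengthCentrality(estimateNetwork(ct))
    for (rule in names(hits)) {
      sel <- suppressWarnings(selectInfluential(cent, rule = rule))
      if ("V1" %in% sel$nodes) hits[rule] <- hits[rule] + 1
    }
  }
  expect_gte(hits[["z_threshold"]], nrep - 1)
  expect_gte(hits[["top_gap"]], nrep - 1)
})
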