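test_that("planted two-clique structure is recovered across seeds", {
  W <- twoCliqueGraph()
  for (s in 1:50) {
    a <- spinglassPartition(W, seed = s)
    expect_equal(a@nCommunities, 2L)
    expect_length(unique(communityLabels(a)[1:4]), 1L)
    expect_length(unique(communityLabels(a)[5:8]), 1L)
  }
})

test_that("a complete positive graph forms one community", {
  W <- matrix(0.5, 5, 5); diag(W) <- 0
  for (s in 1:10)
    expect_equal(spinglassPartition(W, seed = s)@nCommunities, 1L)
})

test_that("a purely negative link is never co-labeled", {
  W <- twoCliqueGraph(extraEdges = list(list(1, 5, -1)))
  for (s in 1:50) {
    lab <- communityLabels(spinglassPartition(W, seed = s))
    expect_false(lab[1] == lab[5])
  }
})

test_that("stored Hamiltonians are exactly recomputable", {
  set.seed(77)
  W <- twoCliqueGraph(extraEdges = list(list(2, 6, -0.4), list(3, 7, 0.2)))
  for (s in c(1, 9, 23)) {
    a <- spinglassPartition(W, seed = s)
    expect_equal(a@hamiltonian,
                 spinglassEnergy(W, communityLabels(a)), tolerance = 1e-12)
  }
  # labels are contiguous from 1
  a <- spinglassPartition(W, seed = 3)
  expect_identical(sort(unique(communityLabels(a))),
                   seq_len(a@nCommunities))
})

test_that("edgeless networks are rejected", {
  expect_error(spinglassPartition(matrix(0, 4, 4)), "edgeless|no edges")
})

test_that("consensus takes the lower median and returns a replaying seed", {
  expect_equal(cytonet:::.lower_median(c(2, 3)), 2)
  expect_equal(cytonet:::.lower_median(c(3, 2, 2, 5)), 2)
  expect_equal(cytonet:::.lower_median(c(4, 2, 3)), 3)

  W <- twoCliqueGraph()
  cc <- consensusCommunityCount(W, runs = 40, seed = 7)
  expect_equal(cc$medianCount, 2L)
  # every run found 2 communities, so the first seed is returned
  expect_equal(cc$reproducingSeed, 7L)
  # replay yields the identical assignment
  replay <- spinglassPartition(W, seed = cc$reproducingSeed)
  expect_identical(communityLabels(replay),
                   communityLabels(cc$assignment))
  expect_equal(replay@hamiltonian, cc$assignment@hamiltonian)
})

test_that("community counts agree with an independent spinglass implementation", {
  W <- twoCliqueGraph(extraEdges = list(list(1, 5, -0.6)))
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(1)
  ref <- igraph::cluster_spinglass(g, implementation = "neg", gamma = 1,
                                   gamma.minus = 1)
  ours <- spinglassPartition(W, seed = 1)
  expect_equal(ours@nCommunities, length(unique(igraph::membership(ref))))
})
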