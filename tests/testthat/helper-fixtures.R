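# shared fixtures, built in code

# symmetric weight matrix from upper-triangle assignments
weightMatrix <- function(p, edges) {
  W <- matrix(0, p, p)
  for (e in edges) W[e[[1]], e[[2]]] <- W[e[[2]], e[[1]]] <- e[[3]]
  dimnames(W) <- list(paste0("N", seq_len(p)), paste0("N", seq_len(p)))
  W
}

# two 4-cliques with unit positive weights and nothing between
twoCliqueGraph <- function(extraEdges = list()) {
  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- 1
  W[5:8, 5:8] <- 1
  diag(W) <- 0
  for (e in extraEdges) W[e[[1]], e[[2]]] <- W[e[[2]], e[[1]]] <- e[[3]]
  W
}

# small cohort with screening CRP and a couple of analysis variables
crpCohort <- function(crp) {
  n <- length(crp)
  d <- cbind(CRP = crp,
             IL6 = seq_len(n) + 0.1,
             TNFa = rev(seq_len(n)) + 0.2)
  CohortTable(d, roles = c("screening", "cytokine", "cytokine"))
}

# a centrality table with prescribed z-scores (strengths engineered so the
# z-standardization reproduces them up to affine rescaling is unnecessary:
# selection rules only read the z column)
centralityWithZ <- function(z, nodes = paste0("N", seq_along(z))) {
  methods::new("CentralityTable",
               table = S4Vectors::DataFrame(
                 node = nodes, strength = z - min(z), z = z,
                 rank = as.integer(rank(-z, ties.method = "min")),
                 degree = rep(1L, length(z)),
                 degreeFraction = rep(0, length(z))))
}
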