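---
title: "Regularized cytokine-symptom networks: models, stability and comparison"
author: "cytonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regularized cytokine-symptom networks: models, stability and comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytonet)
```

# The problem

Immune signalling proteins (cytokines) do not act in isolation: influential
cytokines such as IL-6 regulate the production of others, and their joint
configuration — rather than any single elevated marker — may be what couples
inflammation to particular psychiatric symptoms. cytonet implements the
full analysis chain used in psychometric network studies of such data: a
conditional-dependence network over cytokine concentrations, individual
symptom items and covariates, a measure of each node's influence, a
data-driven decomposition into symptom communities, resampling-based
accuracy and stability diagnostics, and a permutation test comparing
networks between treatment arms or timepoints.

# Network model

Edges are regularized partial correlations. Writing $\Theta$ for the
precision matrix of the variables, the weight of edge $(i, j)$ is

$$ w_{ij} = -\frac{\Theta_{ij}}{\sqrt{\Theta_{ii}\,\Theta_{jj}}}, $$

the correlation between $i$ and $j$ conditional on every other node.
$\Theta$ is estimated by the graphical LASSO: maximize
$\log\det\Theta - \mathrm{tr}(S\Theta) - \lambda \sum_{i \ne j}
|\Theta_{ij}|$, which shrinks small conditional associations to exactly
zero and yields a sparse graph containing only the strongest ones.

Because cytokine concentrations are strongly right-skewed and symptom items
are ordinal Likert scores, $S$ is the Spearman rank correlation matrix
(average ranks for ties). Pairwise-deletion Spearman matrices can be
indefinite, so an eigenvalue-clipping repair (clip at zero, renormalize the
diagonal) is applied before estimation; the repair is idempotent and
recorded in the result. Binary nodes (sex, treatment) are ranked like any
other column — a documented simplification, since rank correlations with
binary variables are interpretable but coarse.

The likelihood above treats the repaired Spearman matrix as if it were a
Gaussian covariance with the observed subject count — a pseudo-likelihood
convention, shared with standard implementations of this estimator, that we
state explicitly rather than hide.

## Penalty selection

$\lambda$ runs over a log-spaced path of 100 values from
$\lambda_{\max}$ (the largest absolute off-diagonal of $S$, floored at
$10^{-4}$) down to $0.01\,\lambda_{\max}$; every $\lambda \ge
\lambda_{\max}$ provably yields the empty graph. The path point minimizing
the Extended Bayesian Information Criterion

$$ \mathrm{EBIC} = -2\ell + E \ln n + 4 E \gamma \ln p $$

is selected, with ties broken toward the sparser (larger-$\lambda$) model.
The hyperparameter $\gamma$ controls the sparsity/discovery trade-off:
$\gamma = 0$ (the package default, matching the discovery-oriented setting
of the analysis this pipeline replicates) reduces the criterion to the BIC
and admits more edges; $\gamma = 0.5$ is the cautious conventional
alternative. The source analysis describes this hyperparameter in a
self-contradictory sentence (calling it $\lambda$ while also contrasting it
with $\lambda = 0$); we read it as the EBIC $\gamma$ set to 0, and expose
$\gamma$ directly so either convention can be run.

## False positives at the path floor, and the `threshold` option

A property worth knowing before interpreting exact edge sets: EBIC
selection along a penalty path can include tiny spurious edges, because
lowering $\lambda$ keeps improving the likelihood of *strong* edges (less
shrinkage bias) and drags small false positives in with them. Two further
facts compound this for rank-based input: the Spearman correlation of a
Gaussian graphical model is a nonlinear transform of its Pearson matrix, so
a partial correlation that is exactly zero on the latent scale is slightly
nonzero on the Spearman scale (about 0.01 for a three-variable chain with
partials of 0.5). Consequently exact support recovery cannot be expected
with raw Spearman input even at large $n$. `estimateNetwork(threshold =
TRUE)` applies the standard remedy — zeroing edges smaller than
$\sqrt{\log(p(p-1)/2)/n}$ after selection — and is recommended whenever the
*edge set*, rather than the weight pattern, is the object of interest. The
default is `FALSE`, faithful to the replication settings.

# Node influence

Strength centrality is the sum of absolute weights of a node's edges;
twice the network's global strength (the sum of all absolute edge weights)
equals the sum of all node strengths. Strengths are z-standardized across
nodes for reporting; when every strength is equal the z-scores are all zero
by convention. "Influential" nodes are selected either by a z threshold
(default 1.0, mirroring the top-scoring pattern reported in this
literature) or by the largest gap in the sorted z sequence — the published
criterion is verbal, so both rules are provided and the selection rule is
recorded in the output.

# Communities

Symptom subgroups are found with a signed spinglass algorithm: the Potts
Hamiltonian rewards co-labelling positively linked nodes and penalizes
co-labelling negatively linked ones, each layer measured against its own
configuration-model null with resolution parameters
$\gamma^+ = \gamma^- = 1$. Minimization is by simulated annealing (start
temperature 1.0, stop 0.01, cooling 0.99, one full Metropolis sweep per
temperature, at most 25 spin states; all overridable). The returned
labeling is the best one visited, its energy is stored and exactly
recomputable, and the run is deterministic given its seed.

Because annealing is stochastic, the pipeline follows the consensus
protocol: run the partitioner 1000 times, take the median community count
(lower median on even ties, so the consensus count is always one that was
realized), and report the first seed that reproduces it — re-running with
that seed regenerates the identical assignment.

# Accuracy and stability

*Edge accuracy.* The nonparametric bootstrap resamples subjects with
replacement (stratified by arm when a treatment node is present),
re-estimates the network with identical settings, and reports how often
each edge was estimated above zero. An edge present in at least 50% of
bootstrap networks is flagged reliable; the boundary value 0.50 qualifies.
Because that published rule is articulated for positive associations, a
sign-agnostic nonzero proportion is reported alongside for negative edges.

*Centrality stability.* The case-dropping bootstrap removes increasing
proportions of subjects (default grid 0.05 to 0.75 in steps of 0.10) and
correlates subsample strength centralities with the full-sample ones. The
CS-coefficient is the largest drop proportion at which at least 95% of
subsample correlations reach 0.70; values below 0.25 indicate unstable
centralities and above 0.5 is ideal. The correlation is Pearson by
default: a rank-based correlation degenerates on networks whose non-hub
strengths are nearly exchangeable — their ranks are pure noise — and
understates stability badly (on planted hub cohorts it reports CS near 0
where the Pearson-based coefficient is 0.75); `corMethod = "spearman"`
remains available.

# Comparing networks

The permutation comparison test re-estimates both networks for randomly
regrouped subjects. The global-strength statistic $S$ is the absolute
difference in global strength; the invariance statistic $M$ is the maximum
absolute edge-weight difference. For independent groups, pooled group
labels are permuted preserving group sizes; for the paired
(baseline-versus-follow-up) design each subject's two condition rows are
swapped with probability one half — the published within-group analyses do
not state their permutation scheme, so the paired variant is flagged
explicitly in the output. P-values use the add-one convention
$(1 + \#\{\text{perm} \ge \text{obs}\})/(1 + N)$ and are never exactly
zero.

When a comparison is significant (default $\alpha = 0.05$), per-node
strength differences and per-edge weight differences are tested against
nulls drawn from the *same* permutation stream as the parent test, with
Holm adjustment across tested edges by default (`"none"` reproduces
unadjusted reporting). Running the post-hoc tables on a non-significant
parent is permitted — degenerate cases such as identical groups are useful
checks — but records a warning that the results are exploratory.

# Synthetic cohorts

No individual-level data from the motivating trial are distributable, so
the package generates cohorts with known ground truth. A planted sparse
precision matrix (unit diagonal; empty, chain, hub, block or custom
topology) defines the truth; if the requested off-diagonals break positive
definiteness they are uniformly shrunk toward the diagonal (bisection to
$10^{-10}$ on the smallest eigenvalue) and the shrink factor is recorded —
magnitudes infeasible even at the shrink floor fail loudly. Latent scores
are multivariate normal with correlation equal to the standardized inverse
of the precision matrix, so the planted partial correlations are exact
population quantities. Each column then passes through a strictly monotone
marginal transform: lognormal-like for skewed cytokine concentrations
(`marginalFromMoments()` matches a published cohort's means and SDs
exactly), ordinal-probit thresholding for Likert items, a single threshold
for binary variables. Monotonicity means the Spearman structure of the
latent network is preserved exactly.

`simulateStudyCohorts()` assembles the full study design: 12 cytokines
with a strongly interconnected pro-inflammatory trio (IL-6, TNF-α, IFN-γ),
9 + 7 + 7 symptom items in depressive/positive/negative blocks, three
hub-to-depressive-item cross edges, covariates, ~95/99 subjects per arm,
screening CRP drawn from a skewed marginal so a realistic few subjects
cross the 10 mg/L exclusion threshold, and a 6-month timepoint in which
the active arm's precision off-diagonals are attenuated (default 0.5,
emulating treatment-induced connectivity loss; attenuation is a convex
combination with the diagonal, so positive definiteness is automatic).
Timepoints share latent innovations with correlation 0.5 — the motivating
study reports no within-subject correlation, so this is the package's own
choice of a moderate, plausible coupling. Base seeds expand to per-arm and
per-timepoint substreams by fixed offsets (arm A: seed+1, arm B: seed+2,
second timepoint: +10), keeping arms independent but reproducible.

What the generator does *not* emulate: assay noise near detection limits,
plate effects, longitudinal autocorrelation beyond the single coupling
parameter, and missingness. Passing recovery tests on these cohorts
therefore demonstrates correctness of the estimation machinery under the
stated generating model, not robustness to those real-data features.

# Numerical choices

- glasso convergence: block coordinate descent on the covariance with
  maintained residuals; outer tolerance $10^{-7}$ scaled by the mean
  absolute off-diagonal of $S$, at most 200 outer iterations,
  non-convergence is an error with diagnostics. Edges below $10^{-10}$
  after convergence count as zero.
- $\lambda = 0$ is solved exactly by matrix inversion (the unpenalized
  maximum-likelihood solution) and requires a positive definite input.
- PSD repair: one eigenvalue-clipping pass with diagonal renormalization;
  inputs whose smallest eigenvalue is above $-10^{-8}$ pass through
  unchanged, making the operation idempotent.
- EBIC ties: resolved toward the larger penalty (sparser model) by strict
  improvement during the path scan.
- Degenerate inputs: constant columns, fewer than 3 usable rows, edgeless
  graphs passed to community detection, and empty influential-node
  selections are reported as errors or warnings at the point of failure.

# Problem sizes used in the test suite

The suite exercises the pipeline at sizes chosen to make the statistical
assertions sharp yet run on a single CPU in minutes: closed-form oracles at
$p \le 6$; recovery at $n = 2000$ over 20 seeds; comparison-test
calibration with 200 null cohort pairs of 150 subjects per arm at $p = 8$
and 500 permutations, checked against exhaustive enumeration on 6-per-arm
instances; stability with 100-200 bootstrap samples; consensus over 1000
annealing runs. The full-protocol sizes (1000 bootstrap samples, 1000
permutations, 1000 consensus runs) are the package defaults.

# Known limitations

- Raw Spearman input makes exact zero-recovery impossible in principle
  (see the path-floor section); interpret tiny edges accordingly or use
  `threshold = TRUE`.
- The pseudo-likelihood convention treats rank correlations as Gaussian
  covariances; $n$ in the EBIC is the subject count (minimum pairwise
  count under pairwise deletion).
- Percentage-change summaries of global strength depend on the chosen
  base; the package reports raw strengths and their difference and leaves
  percentage framing to the analyst, since published percentage figures in
  this literature are not always reconstructible from the printed
  strengths.
- The spinglass annealer is a stochastic heuristic; the consensus protocol
  controls but does not eliminate run-to-run variation on weakly
  structured graphs.

# A minimal session

```{r example, eval = FALSE}
sim <- simulateStudyCohorts(seed = 1)
cfg <- studyConfig(bootstrapB = 200, csB = 100, spinglassRuns = 200,
                   nPermutations = 500, seed = 1,
                   outputDir = "study_out")
report <- runStudyPipeline(cfg, sim)
report$network1$influential$nodes
report$network4$tests$month6Between
```
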