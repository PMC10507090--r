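# cytonet

Regularized partial-correlation network analysis for cytokine–symptom
data from clinical cohorts, with bootstrap stability diagnostics and
permutation-based network comparison.

## The problem

In psychiatric cohorts, inflammation is better described by the joint
configuration of cytokines than by any single elevated marker: influential
cytokines (IL-6 in particular) regulate the production of others, and
their conditional-dependence structure may be what links immune activation
to specific symptoms. `cytonet` implements the standard psychometric
network pipeline for such studies end to end:

1. **Estimation** — Spearman rank correlations (robust to skewed cytokine
   assays and ordinal Likert symptom items), positive-semidefinite repair,
   graphical LASSO over a log-spaced penalty path, and EBIC model
   selection. Edge weights are regularized partial correlations
   `w_ij = -Θ_ij / sqrt(Θ_ii Θ_jj)`.
2. **Influence** — strength centrality `s_i = Σ_j |w_ij|` with z-scores,
   degree fractions, and rule-based selection of influential nodes.
3. **Communities** — signed spinglass (Potts Hamiltonian with
   configuration-model nulls per sign layer, simulated annealing), run to
   a 1000-run median consensus with a reproducing seed.
4. **Stability** — nonparametric edge bootstrap (edges present in ≥ 50% of
   resamples are flagged reliable) and the case-dropping CS-coefficient
   (the largest share of subjects droppable while 95% of subsample
   centralities still correlate ≥ 0.70 with the original).
5. **Comparison** — permutation network comparison test between arms or
   timepoints: global-strength statistic `S = |GS(A) − GS(B)|`, invariance
   statistic `M = max |w_A − w_B|`, add-one p-values, and conditional
   post-hoc strength and edge tests with Holm adjustment.
6. **Synthetic cohorts** — Gaussian-copula generator with planted sparse
   precision structure, skewed/ordinal marginals, two arms, two
   timepoints and a screening-CRP exclusion, so the whole pipeline is
   testable against known ground truth.

## Worked example

```r
library(cytonet)

sim <- simulateStudyCohorts(seed = 7)         # two arms, planted IL-6/TNF-a/IFN-g hub trio
flt <- excludeAcuteInflammation(sim$baseline) # CRP >= 10 mg/L rule
nodes <- assembleNodeSet(flt$cohort, list(cytokines = "all"))
net <- estimateNetwork(nodes$data)            # Spearman -> PSD -> glasso -> EBIC
net
#> NetworkModel: 12 nodes, 52 edges (n = 194, gamma = 0, lambda = 0.02544)
#>   global strength: 4.61
strengthCentrality(net)
#> CentralityTable: 12 nodes
#>   node  strength          z rank degree degreeFraction
#>   IFNg 1.4982235  1.7871481    1     10           90.9
#>    IL6 1.4242085  1.6058126    2     11          100.0
#>   TNFa 1.3807258  1.4992808    3     10           90.9
#>   IL10 0.6623092 -0.2608271    4      8           72.7
#>   ...
selectInfluential(strengthCentrality(net))$zScores
#>      IL6     TNFa     IFNg
#> 1.605813 1.499281 1.787148
```

The three planted hub cytokines stand out with z-scores above 1.0 while
every other cytokine sits below −0.26: the influence ranking recovers the
generating structure. From here, `consensusCommunityCount()` groups
symptoms, `edgeBootstrap()` / `caseDroppingStability()` quantify
reliability, `nct()` compares arms, and `runStudyPipeline()` chains all
four study networks with artifact output. A command-line front end over
the same functions is installed at `inst/scripts/cytonet-cli.R`.

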