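#' @include AllClasses.R cohort.R synth.R estimate.R metrics.R communities.R stability.R compare.R io.R
NULL

#' Study configuration
#'
#' Collects every tunable of the four-network study design: estimator
#' settings, bootstrap sizes, spinglass consensus runs, permutation counts,
#' the CRP exclusion threshold, seeds, and the output directory. Defaults
#' are the reference protocol sizes (1000 bootstrap samples, 1000
#' spinglass runs, 1000 permutations); analyses at reduced scale pass
#' smaller values explicitly.
#'
#' @param gamma EBIC hyperparameter (0 = discovery mode).
#' @param nLambda,minRatio penalty path controls.
#' @param influenceRule,influenceParam influential-node selection rule.
#' @param bootstrapB nonparametric bootstrap samples.
#' @param csB case-dropping subsamples per grid level.
#' @param dropGrid case-dropping proportions.
#' @param spinglassRuns consensus community runs.
#' @param nPermutations NCT permutations.
#' @param alpha significance level for conditional post-hoc tests.
#' @param crpThreshold CRP exclusion threshold in mg/L.
#' @param networks which of networks 1-4 to run.
#' @param seed base seed for all stage RNG streams.
#' @param outputDir artifact directory (\code{NULL} = no files written).
#' @return a named list.
#' @export
studyConfig <- function(gamma = 0, nLambda = 100, minRatio = 0.01,
                        influenceRule = "z_threshold", influenceParam = 1.0,
                        bootstrapB = 1000, csB = 1000,
                        dropGrid = seq(0.05, 0.75, by = 0.10),
                        spinglassRuns = 1000, nPermutations = 1000,
                        alpha = 0.05, crpThreshold = 10, networks = 1:4,
                        seed = 1L, outputDir = NULL) {
  list(gamma = gamma, nLambda = nLambda, minRatio = minRatio,
       influenceRule = influenceRule, influenceParam = influenceParam,
       bootstrapB = bootstrapB, csB = csB, dropGrid = dropGrid,
       spinglassRuns = spinglassRuns, nPermutations = nPermutations,
       alpha = alpha, crpThreshold = crpThreshold, networks = networks,
       seed = as.integer(seed), outputDir = outputDir)
}

# ----------------------------------------------------- synthetic study ------

.CYTOKINES <- c("hsCRP", "IL1RA", "IL1b", "IL2", "IL4", "IL6", "IL8",
                "IL10", "IL12", "IL13", "TNFa", "IFNg")
.CDSS   <- paste0("CDSS", 1:9)
.PANSSP <- paste0("PANSS_P", 1:7)
.PANSSN <- paste0("PANSS_N", 1:7)

#' Ground-truth network for the synthetic study cohort
#'
#' A 38-variable planted structure emulating an inflammatory-symptom
#' cohort: a pro-inflammatory hub trio (IL-6, TNF-alpha, IFN-gamma)
#' strongly interconnected and linked to the remaining cytokines, symptom
#' items grouped into depressive (CDSS), positive (PANSS_P) and negative
#' (PANSS_N) communities, three sparse hub-cytokine-to-depressive-item
#' cross edges, and weak age/BMI links into the cytokine block.
#'
#' @param hubValue precision off-diagonal within the hub trio (default
#'   -0.25, i.e. partial correlations near +0.25).
#' @param blockValue within-community precision off-diagonal (default
#'   -0.12).
#' @param crossValue hub-to-symptom precision off-diagonal (default -0.10).
#' @return a \linkS4class{TrueNetworkSpec} with named variables.
#' @export
studyTrueNetwork <- function(hubValue = -0.25, blockValue = -0.12,
                             crossValue = -0.10) {
  vars <- c(.CYTOKINES, .CDSS, .PANSSP, .PANSSN, "age", "sex", "BMI")
  p <- length(vars)
  M <- matrix(0, p, p, dimnames = list(vars, vars))
  hub <- c("IL6", "TNFa", "IFNg")
  for (a in hub) for (b in hub) if (a != b) M[a, b] <- hubValue
  others <- setdiff(.CYTOKINES, hub)
  # each hub cytokine reaches most of the panel
  for (h in hub) for (o in others) M[h, o] <- M[o, h] <- blockValue
  blockEdges <- function(items) {
    for (i in seq_along(items)[-1])
      M[items[i - 1], items[i]] <<- M[items[i], items[i - 1]] <<- blockValue
    for (i in seq_along(items)[-c(1, 2)])
      M[items[i - 2], items[i]] <<- M[items[i], items[i - 2]] <<- blockValue
  }
  blockEdges(.CDSS); blockEdges(.PANSSP); blockEdges(.PANSSN)
  # hub cytokine to depressive/suspiciousness items
  M["IL6", "CDSS3"] <- M["CDSS3", "IL6"] <- crossValue     # self-deprecation
  M["IFNg", "CDSS2"] <- M["CDSS2", "IFNg"] <- crossValue   # hopelessness
  M["TNFa", "PANSS_P6"] <- M["PANSS_P6", "TNFa"] <- crossValue  # suspiciousness
  M["age", "IL6"] <- M["IL6", "age"] <- crossValue
  M["BMI", "IL6"] <- M["IL6", "BMI"] <- crossValue
  spec <- buildTrueNetwork("custom", p, pattern = M)
  blocks <- c(rep(1L, length(.CYTOKINES)), rep(2L, length(.CDSS)),
              rep(3L, length(.PANSSP)), rep(4L, length(.PANSSN)),
              rep(5L, 3L))
  spec@blockAssignment <- blocks
  spec@precision <- `dimnames<-`(spec@precision, list(vars, vars))
  spec@truePartials <- `dimnames<-`(spec@truePartials, list(vars, vars))
  spec
}

.study_marginals <- function() {
  # cytokine marginals calibrated to published recent-onset schizophrenia
  # cohort moments (pg/mL except hsCRP in mg/L); Likert items via
  # ordinal-probit thresholds; age/BMI mildly skewed continuous
  cyt <- list(
    hsCRP = c(2.52, 2.35), IL1RA = c(407.49, 437.60), IL1b = c(0.07, 0.26),
    IL2 = c(0.23, 0.26), IL4 = c(0.02, 0.02), IL6 = c(0.70, 0.50),
    IL8 = c(4.51, 2.95), IL10 = c(0.44, 0.89), IL12 = c(0.14, 0.16),
    IL13 = c(0.49, 0.48), TNFa = c(2.50, 0.64), IFNg = c(4.80, 5.93))
  m <- lapply(cyt, function(v) marginalFromMoments(v[1], v[2]))
  cdss <- rep(list(marginalOrdinal(thresholds = c(-0.2, 0.8, 1.6),
                                   baseCategory = 0)), 9)
  pan <- rep(list(marginalOrdinal(
    thresholds = c(-1.2, -0.4, 0.3, 1.0, 1.7, 2.4), baseCategory = 1)), 14)
  covs <- list(age = marginalSkewed(location = 25.6, scale = 5.2, shape = 0),
               sex = marginalBinary(prob = 0.258, codes = c(1, 2)),
               BMI = marginalSkewed(location = 27.3, scale = 6.5, shape = 0))
  c(m, cdss, pan, covs)
}

#' Simulate a two-arm, two-timepoint synthetic study cohort
#'
#' Generates baseline and 6-month \linkS4class{CohortTable}s for a
#' placebo-like arm (treatment 1) and an active arm (treatment 2). Both
#' arms share the generating network at baseline; at 6 months the active
#' arm's precision off-diagonals are scaled by \code{attenuation}
#' (connectivity loss under treatment). A subject's two timepoints share
#' latent innovations with correlation \code{pairedCoupling}. Screening
#' CRP is drawn independently from a skewed marginal so a realistic few
#' subjects exceed the 10 mg/L exclusion threshold.
#'
#' @param nPerArm analytic arm sizes (default 95 placebo / 99 active).
#' @param attenuation active-arm 6-month edge attenuation (default 0.5).
#' @param pairedCoupling latent correlation between timepoints (default
#'   0.5).
#' @param truth generating network (default \code{\link{studyTrueNetwork}}).
#' @param seed base seed; arms/timepoints use fixed offsets.
#' @return list with \code{baseline}, \code{month6}
#'   (\linkS4class{CohortTable}s including treatment and, at baseline,
#'   screening CRP), \code{truth} and \code{truthAttenuated}.
#' @export
simulateStudyCohorts <- function(nPerArm = c(95L, 99L), attenuation = 0.5,
                                 pairedCoupling = 0.5,
                                 truth = studyTrueNetwork(), seed = 1L) {
  marg <- .study_marginals()
  vars <- rownames(truth@precision)
  stopifnot(length(marg) == length(vars))
  truthB <- .attenuate(truth, attenuation)
  LA <- chol(.latent_correlation(truth@precision))
  LB <- chol(.latent_correlation(truthB@precision))
  rho <- pairedCoupling
  drawArm <- function(n, armSeed, attenuated) {
    set.seed(as.integer(armSeed))
    U1 <- matrix(rnorm(n * length(vars)), n)
    U2 <- matrix(rnorm(n * length(vars)), n)
    Z1 <- U1 %*% LA
    L2 <- if (attenuated) LB else LA
    Z2 <- (rho * U1 + sqrt(1 - rho^2) * U2) %*% L2
    list(Z1 = Z1, Z2 = Z2)
  }
  a <- drawArm(nPerArm[1], seed + 1L, FALSE)
  b <- drawArm(nPerArm[2], seed + 2L, TRUE)
  roles <- c(rep("cytokine", 12), rep("symptom", 23),
             "covariate", "covariate", "covariate")
  instr <- c(rep(NA, 12), rep("CDSS", 9), rep("PANSS_P", 7),
             rep("PANSS_N", 7), rep(NA, 3))
  applyAll <- function(Z) vapply(seq_along(marg), function(j)
    as.numeric(applyMarginal(marg[[j]], Z[, j])), numeric(nrow(Z)))
  buildTable <- function(Z, timepoint, withCRP) {
    n1 <- nPerArm[1]
    X <- applyAll(Z)
    colnames(X) <- vars
    treatment <- c(rep(1, n1), rep(2, nrow(X) - n1))
    X <- cbind(X, treatment = treatment)
    r <- c(roles, "treatment")
    s <- c(vapply(marg, function(m) switch(m@family,
             skewed_continuous = "continuous", ordinal = "ordinal",
             binary = "binary"), character(1)), "binary")
    ins <- c(instr, NA)
    if (withCRP) {
      crp <- applyMarginal(marginalFromMoments(2.52, 2.35),
                           rnorm(nrow(X)))
      X <- cbind(X, CRP_screen = crp)
      r <- c(r, "screening"); s <- c(s, "continuous"); ins <- c(ins, NA)
    }
    rownames(X) <- sprintf("S%03d", seq_len(nrow(X)))
    CohortTable(X, roles = r, scales = s, instruments = as.character(ins),
                timepoint = timepoint)
  }
  set.seed(as.integer(seed) + 5L)
  baseline <- buildTable(rbind(a$Z1, b$Z1), "baseline", withCRP = TRUE)
  month6 <- buildTable(rbind(a$Z2, b$Z2), "month6", withCRP = FALSE)
  list(baseline = baseline, month6 = month6, truth = truth,
       truthAttenuated = truthB)
}

# ------------------------------------------------------------ pipeline ------

.relevant_symptoms <- function(net, assignment, roleMap, influential) {
  # symptoms belonging to a community linked to an influential cytokine:
  # a community qualifies when at least one nonzero influential-cytokine to
  # symptom edge lands in it (membership of the cytokine itself also counts)
  W <- net@weights
  labs <- assignment@labels
  nm <- net@nodeNames
  sym <- nm[roleMap[nm] == "symptom"]
  qual <- integer(0)
  for (cy in intersect(influential, nm)) {
    partners <- nm[abs(W[cy, ]) > 1e-10]
    qual <- union(qual, labs[intersect(partners, sym)])
    qual <- union(qual, labs[cy])
  }
  sym[labs[sym] %in% qual]
}

.stage <- function(report, name, expr) {
  res <- tryCatch(expr, error = function(e) {
    warning(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    structure(list(error = conditionMessage(e)), class = "stageFailure")
  })
  report[[name]] <- res
  report
}

#' Run the four-network study pipeline
#'
#' Orchestrates the complete design on a baseline / 6-month cohort pair:
#' CRP screening exclusion; Network 1 (all cytokines: estimation, strength
#' centrality, influential selection, edge bootstrap, CS-coefficient);
#' Network 2 (influential cytokines + all symptom items + covariates:
#' estimation, spinglass consensus communities, edge bootstrap, relevant
#' symptom derivation); Network 3 (treatment node + influential cytokines +
#' relevant symptoms + covariates + baseline severity node: estimation,
#' edge bootstrap); Network 4 (per-arm networks: baseline between-arm NCT,
#' within-arm paired NCTs, 6-month between-arm NCT, with post-hoc tests
#' only for significant comparisons). Artifacts and a run manifest are
#' written when \code{config$outputDir} is set.
#'
#' @param config a \code{\link{studyConfig}} list.
#' @param cohorts list with \code{baseline} and (for networks 3-4)
#'   \code{month6} \linkS4class{CohortTable}s, e.g. from
#'   \code{\link{simulateStudyCohorts}}.
#' @return a nested report list; failed stages carry class
#'   \code{"stageFailure"} instead of results.
#' @export
runStudyPipeline <- function(config, cohorts) {
  stopifnot(is.list(cohorts), !is.null(cohorts$baseline))
  report <- list(config = config, notices = character())
  outDir <- config$outputDir
  artifacts <- character()
  emit <- function(fun, obj, file) {
    if (is.null(outDir)) return(invisible(NULL))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(outDir, file)
    fun(obj, path)
    artifacts <<- c(artifacts, path)
  }

  # ---- filter ----
  flt <- excludeAcuteInflammation(cohorts$baseline,
                                  threshold = config$crpThreshold)
  baseline <- flt$cohort
  report$filter <- flt$report
  month6 <- NULL
  if (!is.null(cohorts$month6)) {
    keep <- intersect(subjectIds(cohorts$month6), subjectIds(baseline))
    month6 <- cohorts$month6[, keep]
  }
  roles <- variableRoles(baseline)

  # ---- Network 1: cytokines ----
  influential <- character()
  if (1 %in% config$networks) {
    report <- .stage(report, "network1", {
      nodes <- assembleNodeSet(baseline, list(cytokines = "all"))
      net <- estimateNetwork(nodes$data, gamma = config$gamma,
                             nLambda = config$nLambda,
                             minRatio = config$minRatio)
      cent <- strengthCentrality(net)
      sel <- selectInfluential(cent, rule = config$influenceRule,
                               param = config$influenceParam)
      boot <- edgeBootstrap(nodes$data, B = config$bootstrapB,
                            gamma = config$gamma,
                            nLambda = config$nLambda,
                            minRatio = config$minRatio,
                            seed = config$seed + 11L)
      stab <- caseDroppingStability(nodes$data, dropGrid = config$dropGrid,
                                    B = config$csB, gamma = config$gamma,
                                    nLambda = config$nLambda,
                                    minRatio = config$minRatio,
                                    seed = config$seed + 12L)
      emit(writeNetworkCSV, net, "network1_weights.csv")
      emit(writeEdgeListTSV, net, "network1_edges.tsv")
      emit(writeNetworkGraphML, net, "network1.graphml")
      emit(function(o, f) write.csv(as.data.frame(o), f, row.names = FALSE),
           cent, "network1_centrality.csv")
      list(network = net, centrality = cent, influential = sel,
           bootstrap = boot, stability = stab)
    })
    if (!inherits(report$network1, "stageFailure"))
      influential <- report$network1$influential$nodes
  }

  # ---- Network 2: influential cytokines + all symptoms + covariates ----
  relevant <- character()
  if (2 %in% config$networks && length(influential)) {
    report <- .stage(report, "network2", {
      nodes <- assembleNodeSet(baseline,
                               list(cytokines = influential,
                                    symptoms = "all", covariates = "all"))
      net <- estimateNetwork(nodes$data, gamma = config$gamma,
                             nLambda = config$nLambda,
                             minRatio = config$minRatio)
      cons <- consensusCommunityCount(net, runs = config$spinglassRuns,
                                      seed = config$seed + 21L)
      boot <- edgeBootstrap(nodes$data, B = config$bootstrapB,
                            gamma = config$gamma,
                            nLambda = config$nLambda,
                            minRatio = config$minRatio,
                            seed = config$seed + 22L)
      rel <- .relevant_symptoms(net, cons$assignment, nodes$roles,
                                influential)
      emit(writeNetworkCSV, net, "network2_weights.csv")
      emit(writeNetworkGraphML, net, "network2.graphml")
      emit(function(o, f) write.csv(
        data.frame(node = names(o@labels), community = o@labels), f,
        row.names = FALSE), cons$assignment, "network2_communities.csv")
      list(network = net, consensus = cons, bootstrap = boot,
           relevantSymptoms = rel)
    })
    if (!inherits(report$network2, "stageFailure"))
      relevant <- report$network2$relevantSymptoms
  }

  # ---- Network 3: treatment effects at 6 months ----
  panssItems <- names(roles)[roles == "symptom" &
                               variableInstruments(baseline) %in%
                                 c("PANSS_P", "PANSS_N")]
  if (3 %in% config$networks && !is.null(month6) && length(influential)) {
    report <- .stage(report, "network3", {
      nodes <- assembleNodeSet(
        month6,
        list(cytokines = influential,
             symptoms = relevant, covariates = "all",
             includeTreatment = TRUE,
             severityItems = if (length(panssItems)) panssItems else NULL),
        severityFrom = baseline)
      net <- estimateNetwork(nodes$data, gamma = config$gamma,
                             nLambda = config$nLambda,
                             minRatio = config$minRatio)
      boot <- edgeBootstrap(nodes$data, B = config$bootstrapB,
                            gamma = config$gamma,
                            nLambda = config$nLambda,
                            minRatio = config$minRatio,
                            seed = config$seed + 31L)
      emit(writeNetworkCSV, net, "network3_weights.csv")
      emit(writeNetworkGraphML, net, "network3.graphml")
      list(network = net, bootstrap = boot, roles = nodes$roles)
    })
  } else if (3 %in% config$networks) {
    report$notices <- c(report$notices,
                        "network 3 skipped: needs 6-month data and influential cytokines")
  }

  # ---- Network 4: between/within-group comparisons ----
  if (4 %in% config$networks && !is.null(month6) && length(influential)) {
    report <- .stage(report, "network4", {
      recipe <- list(cytokines = influential, symptoms = relevant,
                     covariates = "all")
      arm <- cohortMatrix(baseline)[, "treatment"]
      mkSplit <- function(tab) {
        nodes <- assembleNodeSet(tab, recipe)
        a <- subjectIds(tab)[cohortMatrix(tab)[, "treatment"] == 1]
        b <- subjectIds(tab)[cohortMatrix(tab)[, "treatment"] == 2]
        list(A = nodes$data[a, , drop = FALSE],
             B = nodes$data[b, , drop = FALSE])
      }
      b0 <- mkSplit(baseline)
      m6 <- mkSplit(month6)
      run <- function(xa, xb, design, seedOff)
        nct(xa, xb, nPermutations = config$nPermutations, design = design,
            gamma = config$gamma, nLambda = config$nLambda,
            minRatio = config$minRatio, alpha = config$alpha,
            seed = config$seed + seedOff)
      res <- list(
        baselineBetween = run(b0$A, b0$B, "independent", 41L),
        withinPlacebo = run(b0$A, m6$A[rownames(b0$A), , drop = FALSE],
                            "paired", 42L),
        withinActive = run(b0$B, m6$B[rownames(b0$B), , drop = FALSE],
                           "paired", 43L),
        month6Between = run(m6$A, m6$B, "independent", 44L))
      posthoc <- list()
      for (nm in names(res)) {
        r <- res[[nm]]
        if (r@pS < config$alpha || r@pM < config$alpha) {
          posthoc[[nm]] <- list(
            strength = posthocStrengthCentrality(r),
            edges = posthocEdgeInvariance(r))
          emit(function(o, f) write.csv(as.data.frame(o), f,
                                        row.names = FALSE),
               posthoc[[nm]]$strength,
               sprintf("network4_%s_posthoc_strength.csv", nm))
          emit(function(o, f) write.csv(as.data.frame(o), f,
                                        row.names = FALSE),
               posthoc[[nm]]$edges,
               sprintf("network4_%s_posthoc_edges.csv", nm))
        }
      }
      list(tests = res, posthoc = posthoc)
    })
  } else if (4 %in% config$networks) {
    report$notices <- c(report$notices,
                        "network 4 skipped: configuration or inputs incomplete")
  }

  # ---- manifest ----
  if (!is.null(outDir)) {
    manifest <- list(
      settings = config[setdiff(names(config), "outputDir")],
      seed = config$seed,
      packageVersion = as.character(utils::packageVersion("cytonet")),
      artifacts = artifacts,
      notices = report$notices)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    report$manifest <- manifest
  }
  report
}
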