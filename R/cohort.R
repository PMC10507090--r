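#' @include AllClasses.R
NULL

#' Construct a CohortTable
#'
#' Wraps a subjects-by-variables data frame or matrix with per-variable role
#' and scale metadata. A treatment variable coded 0/1 is recoded to the 1
#' (placebo) / 2 (active) convention with a warning.
#'
#' @param data data.frame or matrix, one row per subject, one column per
#'   variable.
#' @param roles character vector (one per variable): \code{"cytokine"},
#'   \code{"symptom"}, \code{"covariate"}, \code{"treatment"},
#'   \code{"severity"} or \code{"screening"}.
#' @param scales per-variable scale (\code{"continuous"}, \code{"ordinal"},
#'   \code{"binary"}); guessed from roles when omitted.
#' @param instruments optional instrument tag per variable (e.g.
#'   \code{"CDSS"}, \code{"PANSS_P"}, \code{"PANSS_N"}).
#' @param subjectIds subject identifiers; defaults to row names or
#'   \code{S1..Sn}.
#' @param timepoint optional timepoint tag stored in the object metadata.
#' @return a \linkS4class{CohortTable}.
#' @examples
#' d <- data.frame(IL6 = rlnorm(5), CDSS1 = sample(0:3, 5, TRUE))
#' ct <- CohortTable(d, roles = c("cytokine", "symptom"))
#' cohortMatrix(ct)
#' @export
CohortTable <- function(data, roles, scales = NULL, instruments = NULL,
                        subjectIds = NULL, timepoint = NA_character_) {
  X <- as.matrix(data)
  storage.mode(X) <- "double"
  if (is.null(colnames(X)))
    colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (length(roles) != ncol(X))
    stop("need exactly one role per variable")
  if (!all(roles %in% .ROLES))
    stop("roles must be one of: ", paste(.ROLES, collapse = ", "))
  if (is.null(scales)) {
    scales <- ifelse(roles %in% c("symptom"), "ordinal", "continuous")
    scales[roles == "treatment"] <- "binary"
  }
  if (!all(scales %in% .SCALES))
    stop("scales must be one of: ", paste(.SCALES, collapse = ", "))
  if (is.null(instruments)) instruments <- rep(NA_character_, ncol(X))
  if (is.null(subjectIds)) {
    subjectIds <- rownames(X)
    if (is.null(subjectIds)) subjectIds <- paste0("S", seq_len(nrow(X)))
  }
  tr <- which(roles == "treatment")
  if (length(tr) == 1L) {
    v <- X[, tr]
    if (all(v[!is.na(v)] %in% c(0, 1)) && any(v == 0, na.rm = TRUE)) {
      warning("treatment column coded 0/1; recoding to 1 (placebo) / 2 (active)")
      X[, tr] <- v + 1
    }
  }
  se <- SummarizedExperiment(
    assays = list(values = t(X)),
    rowData = S4Vectors::DataFrame(role = roles, scale = scales,
                                   instrument = instruments,
                                   row.names = colnames(X)),
    colData = S4Vectors::DataFrame(row.names = subjectIds))
  out <- methods::new("CohortTable", se)
  S4Vectors::metadata(out)$timepoint <- timepoint
  validObject(out)
  out
}

#' @describeIn CohortTable subjects-by-variables numeric matrix.
#' @param x a \linkS4class{CohortTable}.
#' @export
cohortMatrix <- function(x) t(assay(x, "values"))

#' @describeIn CohortTable named character vector of variable roles.
#' @export
variableRoles <- function(x) setNames(rowData(x)$role, rownames(x))

#' @describeIn CohortTable named character vector of variable scales.
#' @export
variableScales <- function(x) setNames(rowData(x)$scale, rownames(x))

#' @describeIn CohortTable named character vector of instrument tags.
#' @export
variableInstruments <- function(x) setNames(rowData(x)$instrument, rownames(x))

#' @describeIn CohortTable subject identifiers.
#' @export
subjectIds <- function(x) colnames(x)

#' Subset a cohort to named variables, preserving metadata
#' @param x a \linkS4class{CohortTable}.
#' @param vars variable names to keep (order preserved).
#' @return a \linkS4class{CohortTable}.
#' @export
selectVariables <- function(x, vars) {
  miss <- setdiff(vars, rownames(x))
  if (length(miss))
    stop("variables not present in the cohort: ", paste(miss, collapse = ", "))
  x[vars, ]
}

setMethod("show", "CohortTable", function(object) {
  cat(sprintf("CohortTable: %d subjects x %d variables\n",
              ncol(object), nrow(object)))
  tab <- table(rowData(object)$role)
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  tp <- S4Vectors::metadata(object)$timepoint
  if (!is.null(tp) && !is.na(tp)) cat("  timepoint:", tp, "\n")
})

# ------------------------------------------------------------- filtering ----

#' Exclude subjects with acute-inflammation screening values
#'
#' Removes subjects whose screening C-reactive protein (CRP) is at or above
#' \code{threshold} mg/L; values this high flag possible acute infection
#' that would bias cytokine networks. The boundary value is excluded
#' (\code{>=} rule).
#'
#' @param x a \linkS4class{CohortTable} containing a variable with role
#'   \code{"screening"}.
#' @param threshold exclusion threshold in mg/L (default 10).
#' @param missingPolicy what to do with missing CRP: keep the subject
#'   (\code{"keep"}), drop it (\code{"drop"}), or fail listing the subjects
#'   (\code{"error"}).
#' @return a list with elements \code{cohort} (the filtered
#'   \linkS4class{CohortTable}) and \code{report} (excluded count, retained
#'   count, percentage excluded to one decimal).
#' @examples
#' d <- data.frame(CRP = c(2.5, 10.0, 9.9), IL6 = c(1, 2, 3))
#' ct <- CohortTable(d, roles = c("screening", "cytokine"))
#' excludeAcuteInflammation(ct)$report
#' @export
excludeAcuteInflammation <- function(x, threshold = 10,
                                     missingPolicy = c("keep", "drop",
                                                       "error")) {
  missingPolicy <- match.arg(missingPolicy)
  stopifnot(threshold > 0)
  idx <- which(rowData(x)$role == "screening")
  if (length(idx) == 0L)
    stop("no screening (CRP) variable present in the cohort")
  crp <- assay(x, "values")[idx[1L], ]
  if (anyNA(crp)) {
    if (missingPolicy == "error")
      stop("missing screening CRP for subjects: ",
           paste(colnames(x)[is.na(crp)], collapse = ", "))
    if (missingPolicy == "drop") crp[is.na(crp)] <- Inf
    else crp[is.na(crp)] <- -Inf
  }
  keep <- crp < threshold
  nTot <- length(keep)
  report <- list(
    total = nTot,
    excluded = sum(!keep),
    retained = sum(keep),
    pctExcluded = round(100 * sum(!keep) / nTot, 1),
    threshold = threshold)
  list(cohort = x[, keep], report = report)
}

# ------------------------------------------------------------- node sets ----

#' Assemble an analysis node set from a cohort
#'
#' Builds the column-ordered analysis matrix for one network recipe. The
#' deterministic ordering is: cytokines, symptoms by instrument (CDSS, then
#' PANSS_P, then PANSS_N, then untagged), covariates, treatment, severity.
#' A severity node, when requested, is the sum of the named symptom items
#' (e.g. the PANSS total).
#'
#' @param x a \linkS4class{CohortTable}.
#' @param recipe list with optional elements:
#'   \describe{
#'     \item{cytokines}{character vector of cytokine variables (or
#'       \code{"all"}).}
#'     \item{symptoms}{symptom variables, \code{"all"}, or instrument names
#'       (e.g. \code{c("CDSS", "PANSS_P")}).}
#'     \item{covariates}{covariate variables or \code{"all"}.}
#'     \item{includeTreatment}{logical.}
#'     \item{severityItems}{symptom items to sum into a severity node named
#'       \code{severityName} (default \code{"PANSS_total"}); items may come
#'       from a different (e.g. baseline) cohort via \code{severityFrom}.}
#'   }
#' @param severityFrom optional second \linkS4class{CohortTable} supplying
#'   the severity items (matched by subject id).
#' @return list with \code{data} (subjects x variables matrix) and
#'   \code{roles} (named role vector).
#' @export
assembleNodeSet <- function(x, recipe, severityFrom = NULL) {
  roles <- variableRoles(x)
  instr <- variableInstruments(x)
  pick <- function(request, role) {
    have <- names(roles)[roles == role]
    if (is.null(request)) return(character())
    if (identical(request, "all")) return(have)
    if (role == "symptom") {
      inst <- intersect(request, unique(instr[!is.na(instr)]))
      byInst <- names(roles)[roles == "symptom" & instr %in% inst]
      direct <- intersect(request, have)
      out <- unique(c(byInst, direct))
      bad <- setdiff(request, c(inst, have))
      if (length(bad))
        stop("recipe names absent symptom variables/instruments: ",
             paste(bad, collapse = ", "))
      return(out)
    }
    bad <- setdiff(request, have)
    if (length(bad))
      stop("recipe names absent ", role, " variables: ",
           paste(bad, collapse = ", "))
    request
  }
  cyt <- pick(recipe$cytokines, "cytokine")
  sym <- pick(recipe$symptoms, "symptom")
  # symptoms ordered by instrument
  instOrder <- c("CDSS", "PANSS_P", "PANSS_N")
  symOrd <- unlist(lapply(instOrder, function(ins) sym[instr[sym] %in% ins]))
  symOrd <- c(symOrd, setdiff(sym, symOrd))
  cov <- pick(recipe$covariates, "covariate")
  sel <- c(cyt, symOrd, cov)
  if (anyDuplicated(sel))
    stop("duplicate variables requested in recipe: ",
         paste(unique(sel[duplicated(sel)]), collapse = ", "))
  X <- cohortMatrix(x)[, sel, drop = FALSE]
  roleMap <- roles[sel]
  if (isTRUE(recipe$includeTreatment)) {
    tvar <- names(roles)[roles == "treatment"]
    if (length(tvar) != 1L)
      stop("recipe requests a treatment node but the cohort has none")
    tv <- cohortMatrix(x)[, tvar]
    if (all(tv[!is.na(tv)] %in% c(0, 1)) && any(tv == 0, na.rm = TRUE)) {
      warning("treatment column coded 0/1; recoding to 1 (placebo) / 2 (active)")
      tv <- tv + 1
    }
    X <- cbind(X, tv)
    colnames(X)[ncol(X)] <- tvar
    roleMap <- c(roleMap, setNames("treatment", tvar))
  }
  if (!is.null(recipe$severityItems)) {
    src <- if (is.null(severityFrom)) x else severityFrom
    items <- recipe$severityItems
    miss <- setdiff(items, rownames(src))
    if (length(miss))
      stop("severity items absent from the cohort: ",
           paste(miss, collapse = ", "))
    sv <- rowSums(cohortMatrix(src)[subjectIds(x), items, drop = FALSE])
    nm <- if (is.null(recipe$severityName)) "PANSS_total" else recipe$severityName
    X <- cbind(X, sv)
    colnames(X)[ncol(X)] <- nm
    roleMap <- c(roleMap, setNames("severity", nm))
  }
  list(data = X, roles = roleMap)
}
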