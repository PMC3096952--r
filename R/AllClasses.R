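#' SurvivalCohort: patient covariates with survival outcome
#'
#' A [SummarizedExperiment::SummarizedExperiment]-derived container holding
#' one assay, `"scores"`, with modeling variables as rows and patients as
#' columns, plus per-patient follow-up time in years (`time_years`) and a
#' cause-specific event indicator (`event`; 1 = death from disease,
#' 0 = censored) in `colData`.  Additional `colData` columns may carry
#' stratum information (e.g. receptor status) that is not a modeling
#' variable.
#'
#' Subsetting works as for any SummarizedExperiment: `cohort[, idx]` keeps a
#' patient subset (a cross-validation fold), `cohort[vars, ]` a variable
#' subset.
#'
#' @slot .  Inherits all SummarizedExperiment slots.
#' @exportClass SurvivalCohort
setClass("SurvivalCohort", contains = "SummarizedExperiment")

setValidity("SurvivalCohort", function(object) {
  msg <- character(0)
  if (!"scores" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'scores' is required")
  cd <- colData(object)
  if (!all(c("time_years", "event") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'time_years' and 'event'")
  else {
    tm <- cd$time_years
    ev <- cd$event
    if (any(!is.finite(tm)) || any(tm <= 0))
      msg <- c(msg, "time_years must be finite and strictly positive")
    if (!all(ev %in% c(0, 1)))
      msg <- c(msg, "event must be 0 or 1")
  }
  if ("scores" %in% SummarizedExperiment::assayNames(object)) {
    sc <- assay(object, "scores")
    if (anyNA(sc))
      msg <- c(msg, "covariate matrix contains missing values; apply complete-case filtering first")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
      msg <- c(msg, "variable names must be present and unique")
  }
  if (length(msg)) msg else TRUE
})

#' CoxFit: a fitted Cox proportional-hazards model
#'
#' Maximum partial-likelihood estimates (Breslow handling of tied event
#' times) for a named variable subset, on raw (unstandardised) covariates.
#'
#' @slot variables Ordered character vector of the fitted variable subset.
#' @slot beta Named numeric, log hazard ratio per unit of each variable.
#' @slot vcov Variance-covariance matrix of `beta` (inverse information).
#' @slot logPartialLikelihood Breslow partial log-likelihood at the optimum.
#' @slot nullLogLik Partial log-likelihood at `beta = 0`.
#' @slot converged Logical; `FALSE` for degenerate or non-convergent fits.
#' @slot nEventsUsed Number of events in the training data.
#' @slot diagnostics Character; reason when `converged` is `FALSE`.
#' @exportClass CoxFit
setClass("CoxFit",
  representation(
    variables = "character",
    beta = "numeric",
    vcov = "matrix",
    logPartialLikelihood = "numeric",
    nullLogLik = "numeric",
    converged = "logical",
    nEventsUsed = "integer",
    diagnostics = "character"
  )
)

setValidity("CoxFit", function(object) {
  if (object@converged && any(!is.finite(object@beta)))
    return("converged fit must have finite coefficients")
  TRUE
})

#' ATDScore: an average time-dependent AUCROC
#'
#' @slot value Mean of the per-event staircase AUCs, in `[0, 1]`.
#' @slot nEventsAveraged Number of death events contributing (multiplicity
#'   counted; events whose case or control set is empty are excluded).
#' @slot curve data.frame with one row per distinct event time:
#'   `event_time`, `n_cases`, `n_controls`, `n_deaths`, `auc_at_time`,
#'   `included`.
#' @exportClass ATDScore
setClass("ATDScore",
  representation(value = "numeric", nEventsAveraged = "integer",
                 curve = "data.frame")
)

#' NestedModelPath: elimination-ordered variable list
#'
#' The result of backward elimination: a permutation of the variable set in
#' which the model of size `m` is exactly the first `m` entries (the last
#' surviving variable sits on top, the first-eliminated at the bottom).
#'
#' @slot orderedVariables Character permutation of the input variables.
#' @exportClass NestedModelPath
setClass("NestedModelPath",
  representation(orderedVariables = "character")
)

setValidity("NestedModelPath", function(object) {
  if (anyDuplicated(object@orderedVariables))
    return("orderedVariables must be a permutation (no duplicates)")
  TRUE
})

#' FoldPlan: reproducible nested fold assignments
#'
#' Event-stratified outer and inner fold assignments for every repeat,
#' regenerable from the seed.
#'
#' @slot nRepeats,nOuter,nInner Integers describing the design.
#' @slot seed Integer master seed.
#' @slot assignments List (one element per repeat) of
#'   `list(outer = <int vector over patients>, inner = <list of nOuter int
#'   vectors, NA at outer-test positions>)`.
#' @exportClass FoldPlan
setClass("FoldPlan",
  representation(nRepeats = "integer", nOuter = "integer",
                 nInner = "integer", seed = "integer",
                 assignments = "list")
)

#' InnerSummary: result of one inner cross-validation loop
#'
#' @slot records data.frame of the inner reduced models, one row per
#'   evaluable inner fold: `fold`, `size`, `score` (inner ATD-AUCROC h) and
#'   a list-column `variables`.
#' @slot expectedSize Performance-weighted expected model size (real-valued,
#'   pre-rounding).
#' @slot stability Named numeric: per-variable h-weighted stability in
#'   `[0, 1]`.
#' @slot frequency Named numeric: unweighted fraction of inner reduced
#'   models containing each variable.
#' @slot skippedFolds Integer vector of inner folds skipped as unevaluable.
#' @exportClass InnerSummary
setClass("InnerSummary",
  representation(records = "data.frame", expectedSize = "numeric",
                 stability = "numeric", frequency = "numeric",
                 skippedFolds = "integer")
)

#' CVSummary: aggregate result of the nested cross-validation
#'
#' @slot reducedScores,fullScores Outer-test ATD-AUCROC (k) per evaluated
#'   repeat x outer fold, for the reduced and the full model.
#' @slot reducedTrainScores,fullTrainScores The same models scored on their
#'   outer training sets (overfitting diagnostic).
#' @slot outerRecords data.frame of outer reduced models: `repeat_id`,
#'   `outer_fold`, `size` (s), `score` (k), `train_score`, list-column
#'   `variables`.
#' @slot innerRecords data.frame of all inner reduced models (audit trail):
#'   `repeat_id`, `outer_fold`, `inner_fold`, `size`, `score`, list-column
#'   `variables`, plus the run-time `expected_size` of their inner loop.
#' @slot frequencyStability Named numeric: fraction of outer reduced models
#'   containing each variable.
#' @slot weightedStability Named numeric: k-weighted variant.
#' @slot finalModel Character: variables of the aggregated final model.
#' @slot variables Character: the declared full variable set.
#' @slot skipped data.frame log of unevaluable folds.
#' @slot nRepeats,seed Run metadata.
#' @exportClass CVSummary
setClass("CVSummary",
  representation(
    reducedScores = "numeric", fullScores = "numeric",
    reducedTrainScores = "numeric", fullTrainScores = "numeric",
    outerRecords = "data.frame", innerRecords = "data.frame",
    frequencyStability = "numeric", weightedStability = "numeric",
    finalModel = "character", variables = "character",
    skipped = "data.frame", nRepeats = "integer", seed = "integer"
  )
)

#' CovariateSpec: distribution and effect of one synthetic covariate
#'
#' @slot name Variable identifier.
#' @slot kind One of `aqua_marker`, `ihc_marker`, `clinical_binary`,
#'   `clinical_ordinal`, `clinical_continuous`.
#' @slot params Named list of distribution parameters (see
#'   [covariateSpec()]).
#' @slot trueBeta Log hazard ratio per unit; 0 for null variables.
#' @exportClass CovariateSpec
setClass("CovariateSpec",
  representation(name = "character", kind = "character",
                 params = "list", trueBeta = "numeric")
)

.covariateKinds <- c("aqua_marker", "ihc_marker", "clinical_binary",
                     "clinical_ordinal", "clinical_continuous")

setValidity("CovariateSpec", function(object) {
  msg <- character(0)
  if (!object@kind %in% .covariateKinds)
    msg <- c(msg, sprintf("kind must be one of %s",
                          paste(.covariateKinds, collapse = ", ")))
  if (!is.finite(object@trueBeta))
    msg <- c(msg, "trueBeta must be finite")
  if (object@kind %in% c("ihc_marker", "clinical_ordinal")) {
    pr <- object@params$probs
    if (is.null(pr) || abs(sum(pr) - 1) > 1e-8 || any(pr < 0))
      msg <- c(msg, sprintf("category probabilities of '%s' must be non-negative and sum to 1",
                            object@name))
  }
  if (object@kind == "clinical_binary") {
    p <- object@params$p
    if (is.null(p) || p < 0 || p > 1)
      msg <- c(msg, sprintf("binary probability of '%s' must lie in [0, 1]", object@name))
  }
  if (length(msg)) msg else TRUE
})

#' CohortSpec: full description of a synthetic survival cohort
#'
#' @slot nPatients Number of patients (>= 2).
#' @slot covariates List of [CovariateSpec-class] objects.
#' @slot baseline Named list: `family` (`"exponential"` or `"weibull"`) plus
#'   `rate` (exponential) or `shape`/`scale` (Weibull), in years.
#' @slot censoring Named list: `type = "uniform"`, `max` (upper bound of the
#'   independent uniform censoring time, years).
#' @slot horizonYears Administrative truncation horizon (> 0).
#' @slot correlation Rank-correlation matrix imposed through a Gaussian
#'   copula, or a 0x0 matrix for independence.
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(nPatients = "integer", covariates = "list",
                 baseline = "list", censoring = "list",
                 horizonYears = "numeric", correlation = "matrix")
)

setValidity("CohortSpec", function(object) {
  msg <- character(0)
  if (object@nPatients < 2L)
    msg <- c(msg, "nPatients must be >= 2")
  if (object@horizonYears <= 0)
    msg <- c(msg, "horizonYears must be > 0")
  if (!length(object@covariates))
    msg <- c(msg, "at least one covariate is required")
  else {
    ok <- vapply(object@covariates, is, logical(1), class2 = "CovariateSpec")
    if (!all(ok)) msg <- c(msg, "covariates must be CovariateSpec objects")
    else {
      nm <- vapply(object@covariates, function(x) x@name, character(1))
      if (anyDuplicated(nm)) msg <- c(msg, "covariate names must be unique")
    }
  }
  fam <- object@baseline$family
  if (is.null(fam) || !fam %in% c("exponential", "weibull"))
    msg <- c(msg, "baseline$family must be 'exponential' or 'weibull'")
  p <- length(object@covariates)
  if (nrow(object@correlation) > 0) {
    cm <- object@correlation
    if (nrow(cm) != p || ncol(cm) != p)
      msg <- c(msg, "correlation matrix dimension must match the number of covariates")
    else if (max(abs(cm - t(cm))) > 1e-8)
      msg <- c(msg, "correlation matrix must be symmetric")
    else if (min(eigen(cm, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      msg <- c(msg, "correlation matrix must be positive semi-definite")
  }
  if (length(msg)) msg else TRUE
})

#' ComparisonResult: two-sided Mann-Whitney comparison of score samples
#'
#' @slot uStatistic Mann-Whitney U of the first sample (ties counted 1/2).
#' @slot pValue Two-sided p-value.
#' @slot nA,nB Sample sizes.
#' @slot direction `"a"`, `"b"` or `"tie"`: which sample has the larger
#'   mean.
#' @slot method `"exact"` (full enumeration) or `"normal"` (tie-corrected
#'   normal approximation).
#' @exportClass ComparisonResult
setClass("ComparisonResult",
  representation(uStatistic = "numeric", pValue = "numeric",
                 nA = "integer", nB = "integer",
                 direction = "character", method = "character")
)
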