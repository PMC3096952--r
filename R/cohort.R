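#' Construct a SurvivalCohort
#'
#' @param covariates Numeric matrix or data.frame, patients in rows and
#'   modeling variables in columns (raw scores; no standardisation is applied
#'   anywhere in the package).
#' @param time Follow-up per patient in years, strictly positive.
#' @param event Cause-specific event indicator per patient (1 = death from
#'   disease, 0 = censored).
#' @param strata Optional data.frame of extra per-patient columns (receptor
#'   status, NPI components ...) kept alongside but not modeled.
#' @return A [SurvivalCohort-class].
#' @examples
#' coh <- SurvivalCohort(
#'   covariates = cbind(marker = c(1, 2, 3, 4)),
#'   time = c(2, 5, 9, 14), event = c(1, 0, 1, 0))
#' survTime(coh)
#' @export
SurvivalCohort <- function(covariates, time, event, strata = NULL) {
  covariates <- as.matrix(covariates)
  if (is.null(colnames(covariates)))
    colnames(covariates) <- paste0("V", seq_len(ncol(covariates)))
  n <- nrow(covariates)
  if (length(time) != n || length(event) != n)
    stop("'time' and 'event' must have one entry per patient (row of 'covariates')")
  pid <- rownames(covariates)
  if (is.null(pid)) pid <- paste0("P", seq_len(n))
  cd <- DataFrame(time_years = as.numeric(time), event = as.numeric(event),
                  row.names = pid)
  if (!is.null(strata)) {
    strata <- as.data.frame(strata)
    if (nrow(strata) != n) stop("'strata' must have one row per patient")
    cd <- cbind(cd, DataFrame(strata))
  }
  se <- SummarizedExperiment(
    assays = list(scores = t(covariates)),
    colData = cd)
  new("SurvivalCohort", se)
}

#' @rdname SurvivalCohort
#' @export
setMethod("survTime", "SurvivalCohort", function(x) {
  setNames(colData(x)$time_years, colnames(x))
})

#' @rdname SurvivalCohort
#' @export
setMethod("survEvent", "SurvivalCohort", function(x) {
  setNames(colData(x)$event, colnames(x))
})

#' @rdname SurvivalCohort
#' @export
setMethod("variableNames", "SurvivalCohort", function(x) rownames(x))

#' @rdname SurvivalCohort
#' @export
setMethod("nPatients", "SurvivalCohort", function(x) ncol(x))

#' @rdname SurvivalCohort
#' @export
setMethod("covariateMatrix", "SurvivalCohort", function(x) {
  t(assay(x, "scores"))
})

#' @describeIn SurvivalCohort Compact display.
#' @export
setMethod("show", "SurvivalCohort", function(object) {
  ev <- survEvent(object)
  cat(sprintf("SurvivalCohort: %d patients, %d variables, %d events (%.1f%%)\n",
              ncol(object), nrow(object), sum(ev),
              if (length(ev)) 100 * mean(ev) else 0))
  cat(sprintf("  follow-up (years): %.2f - %.2f\n",
              min(survTime(object)), max(survTime(object))))
  cat("  variables:", paste(utils::head(rownames(object), 8), collapse = ", "),
      if (nrow(object) > 8) "..." else "", "\n")
})

#' Administratively truncate the endpoint at a horizon
#'
#' Patients followed beyond `horizonYears` are censored at the horizon
#' (time set to the horizon, event to 0).  Events occurring exactly at the
#' horizon are kept as events; only times strictly beyond it are affected,
#' so the operation is idempotent and never drops a patient.
#'
#' @param cohort A [SurvivalCohort-class].
#' @param horizonYears Positive truncation horizon (default 15, the
#'   15-year breast-cancer-specific survival endpoint).
#' @return A new SurvivalCohort; the input is not modified.
#' @export
prepareEndpoint <- function(cohort, horizonYears = 15) {
  if (!is.numeric(horizonYears) || length(horizonYears) != 1 ||
      !is.finite(horizonYears) || horizonYears <= 0)
    stop("'horizonYears' must be a single positive number")
  cd <- colData(cohort)
  over <- cd$time_years > horizonYears
  cd$event[over] <- 0
  cd$time_years[over] <- horizonYears
  colData(cohort) <- cd
  cohort
}

#' Binarize patient age at a cutoff
#'
#' Replaces the age variable by the indicator `age < cutoff` (1 for younger
#' patients), the "Age <50 years" coding conventional in breast-cancer
#' prognostic modeling.
#'
#' @param cohort A [SurvivalCohort-class].
#' @param cutoff Age cutoff in years (default 50).
#' @param ageVar Name of the age row (default `"age"`).
#' @return A new SurvivalCohort with the age row replaced by the indicator.
#' @export
binarizeAge <- function(cohort, cutoff = 50, ageVar = "age") {
  if (!ageVar %in% rownames(cohort))
    stop(sprintf("age variable '%s' not present in the cohort", ageVar))
  sc <- assay(cohort, "scores")
  sc[ageVar, ] <- as.numeric(sc[ageVar, ] < cutoff)
  SummarizedExperiment::assay(cohort, "scores") <- sc
  cohort
}
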