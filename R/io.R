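#' Read a cohort from delimited text
#'
#' Reads the CSV layout written by [writeCohort()]: one row per patient,
#' covariate columns plus a follow-up time column and an event column.
#' Rows with missing values in any used column are dropped (complete-case
#' filtering) with a message reporting the count.
#'
#' @param path CSV file with a header row.
#' @param timeCol,eventCol Column roles (defaults `"time_years"`,
#'   `"event"`).
#' @param variables Modeling variable columns; default: every column that
#'   is not the time, event or a stratum column.
#' @param strataCols Optional columns kept as per-patient strata metadata.
#' @return A [SurvivalCohort-class].
#' @export
readCohort <- function(path, timeCol = "time_years", eventCol = "event",
                       variables = NULL, strataCols = NULL) {
  df <- read.csv(path, check.names = FALSE)
  for (col in c(timeCol, eventCol, variables, strataCols)) {
    if (!col %in% names(df))
      stop(sprintf("column '%s' not found in %s", col, path))
  }
  if (is.null(variables))
    variables <- setdiff(names(df), c(timeCol, eventCol, strataCols))
  used <- df[, c(variables, timeCol, eventCol), drop = FALSE]
  bad <- vapply(used, function(x) !is.numeric(x), logical(1))
  if (any(bad))
    stop("non-numeric columns: ", paste(names(used)[bad], collapse = ", "))
  complete <- stats::complete.cases(used)
  if (sum(complete) == 0) stop("no usable rows after complete-case filtering")
  if (any(!complete))
    message(sprintf("readCohort: dropped %d of %d rows with missing values",
                    sum(!complete), nrow(df)))
  df <- df[complete, , drop = FALSE]
  SurvivalCohort(covariates = as.matrix(df[, variables, drop = FALSE]),
                 time = df[[timeCol]], event = df[[eventCol]],
                 strata = if (is.null(strataCols)) NULL else
                   df[, strataCols, drop = FALSE])
}

#' Write a cohort as delimited text
#'
#' One row per patient: covariate columns, any stratum columns, then
#' `time_years` and `event`.  Comma-separated, header row, `.` decimal.
#'
#' @param cohort A [SurvivalCohort-class].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeCohort <- function(cohort, path) {
  df <- as.data.frame(covariateMatrix(cohort))
  cd <- as.data.frame(colData(cohort))
  extra <- setdiff(names(cd), c("time_years", "event"))
  df <- cbind(df, cd[, extra, drop = FALSE],
              time_years = cd$time_years, event = cd$event)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize / restore a cohort specification (YAML)
#'
#' @param spec A [CohortSpec-class].
#' @param path YAML file path.
#' @return `writeCohortSpec` returns `path` invisibly; `readCohortSpec`
#'   returns the restored [CohortSpec-class].
#' @export
writeCohortSpec <- function(spec, path) {
  covs <- lapply(spec@covariates, function(s)
    c(list(name = s@name, kind = s@kind, true_beta = s@trueBeta), s@params))
  obj <- list(
    n_patients = spec@nPatients,
    horizon_years = spec@horizonYears,
    baseline = spec@baseline,
    censoring = spec@censoring,
    covariates = covs)
  if (nrow(spec@correlation) > 0)
    obj$correlation <- apply(spec@correlation, 1, as.numeric, simplify = FALSE)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname writeCohortSpec
#' @export
readCohortSpec <- function(path) {
  obj <- yaml::read_yaml(path)
  covs <- lapply(obj$covariates, function(s) {
    params <- s[setdiff(names(s), c("name", "kind", "true_beta"))]
    params <- lapply(params, function(x) if (is.list(x)) unlist(x) else x)
    do.call(covariateSpec,
            c(list(name = s$name, kind = s$kind, trueBeta = s$true_beta),
              params))
  })
  corr <- if (!is.null(obj$correlation))
    do.call(rbind, lapply(obj$correlation, as.numeric)) else NULL
  cohortSpec(nPatients = obj$n_patients, covariates = covs,
             baseline = obj$baseline, censoring = obj$censoring,
             horizonYears = obj$horizon_years, correlation = corr)
}

#' Write tabular reports for a nested cross-validation run
#'
#' Emits the tabular twin of the usual three-panel summary: the outer score
#' distributions (test and training side, full and reduced), the reduced
#' model size distribution, the per-variable stability table (frequency and
#' ATD-weighted), the final model as JSON, optional model comparisons, and
#' a manifest (seed, repeats, variable set, package version) sufficient to
#' reproduce the run.  All outputs are deterministic given the summary.
#'
#' @param summary A [CVSummary-class].
#' @param outDir Output directory (created if needed).
#' @param comparisons Optional named list of [ComparisonResult-class]
#'   objects to tabulate.
#' @return Character vector of the files written, invisibly.
#' @export
writeReports <- function(summary, outDir, comparisons = NULL) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  files <- character(0)
  w <- function(df, name) {
    f <- file.path(outDir, name)
    write.csv(df, f, row.names = FALSE)
    files <<- c(files, f)
  }
  rec <- summary@outerRecords
  scores <- rbind(
    data.frame(model = "reduced", repeat_id = rec$repeat_id,
               outer_fold = rec$outer_fold, test_score = summary@reducedScores,
               train_score = summary@reducedTrainScores),
    data.frame(model = "full", repeat_id = rec$repeat_id,
               outer_fold = rec$outer_fold, test_score = summary@fullScores,
               train_score = summary@fullTrainScores))
  w(scores, "score_distributions.csv")
  w(data.frame(size = as.integer(names(table(rec$size))),
               count = as.integer(table(rec$size))),
    "model_size_distribution.csv")
  w(stabilityTable(summary), "stability.csv")
  if (!is.null(comparisons)) {
    cmp <- do.call(rbind, lapply(names(comparisons), function(nm) {
      x <- comparisons[[nm]]
      data.frame(comparison = nm, u_statistic = x@uStatistic,
                 p_value = x@pValue, n_a = x@nA, n_b = x@nB,
                 direction = x@direction, method = x@method)
    }))
    w(cmp, "comparisons.csv")
  }
  fm <- file.path(outDir, "final_model.json")
  jsonlite::write_json(
    list(variables = summary@finalModel,
         size = length(summary@finalModel),
         mean_reduced_score = mean(summary@reducedScores),
         mean_full_score = mean(summary@fullScores)),
    fm, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, fm)
  mf <- file.path(outDir, "manifest.json")
  jsonlite::write_json(
    list(seed = summary@seed, n_repeats = summary@nRepeats,
         variables = summary@variables,
         n_outer_records = nrow(rec),
         n_skipped_folds = nrow(summary@skipped),
         package = "prognest",
         version = as.character(packageVersion("prognest"))),
    mf, auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, mf)
  if (nrow(summary@skipped)) w(summary@skipped, "skipped_folds.csv")
  invisible(files)
}
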