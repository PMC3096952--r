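# Internal: extract a time-sorted design for repeated fitting.  The design
# keeps the assay orientation (variables x patients) with patients sorted by
# increasing follow-up time; the C++ fitter selects active variables by row
# index, so the elimination loop never copies submatrices.
.coxData <- function(cohort, variables = variableNames(cohort)) {
  miss <- setdiff(variables, rownames(cohort))
  if (length(miss))
    stop("variables not present in the cohort: ", paste(miss, collapse = ", "))
  Xt <- assay(cohort, "scores")[variables, , drop = FALSE]
  tm <- colData(cohort)$time_years
  ev <- colData(cohort)$event
  o <- order(tm)
  list(Xt = Xt[, o, drop = FALSE], time = tm[o], status = as.numeric(ev[o]),
       variables = variables)
}

# Internal: fit on a prepared .coxData design, selecting variables by index.
.coxFitRaw <- function(cd, cols = seq_along(cd$variables), init = NULL,
                       wantVcov = TRUE, tol = 1e-10, maxIter = 30L) {
  .cox_fit_breslow(cd$Xt, cd$time, cd$status, cols - 1L, init,
                   maxIter = maxIter, tol = tol, wantVcov = wantVcov)
}

#' Fit a multivariate Cox proportional-hazards model
#'
#' Maximum partial-likelihood estimation with the Breslow approximation for
#' tied event times, on raw (unstandardised) covariate values.  Degenerate
#' inputs (constant covariates, monotone likelihood) yield a fit flagged
#' `converged = FALSE` with a diagnostic rather than an error, so selection
#' loops can treat the candidate as unusable (likelihood `-Inf`).
#'
#' @param cohort A [SurvivalCohort-class] with at least 2 events.
#' @param variables Non-empty character vector of variables to fit.
#' @return A [CoxFit-class].
#' @examples
#' spec <- oncotypeCohortSpec(nPatients = 200)
#' coh <- prepareEndpoint(generateCohort(spec, seed = 1))
#' fitCox(coh, c("AURKA", "nodal_status"))
#' @export
fitCox <- function(cohort, variables = variableNames(cohort)) {
  if (!length(variables)) stop("'variables' must be non-empty")
  nev <- sum(colData(cohort)$event)
  if (nev < 2) stop("at least 2 events are required to fit a Cox model")
  cd <- .coxData(cohort, variables)
  f <- .coxFitRaw(cd, tol = 1e-14, maxIter = 60L)  # reported estimates: tight
  beta <- as.numeric(f$beta)
  names(beta) <- variables
  vc <- if (is.null(f$vcov))
    matrix(NA_real_, length(variables), length(variables)) else f$vcov
  dimnames(vc) <- list(variables, variables)
  new("CoxFit", variables = variables, beta = beta, vcov = vc,
      logPartialLikelihood = as.numeric(f$loglik),
      nullLogLik = as.numeric(f$loglik0),
      converged = isTRUE(f$converged), nEventsUsed = as.integer(nev),
      diagnostics = f$diagnostics)
}

#' @describeIn fitCox Display method for fitted models.
#' @param object A CoxFit.
#' @export
setMethod("show", "CoxFit", function(object) {
  cat(sprintf("CoxFit (%d variables, %d events, %s)\n",
              length(object@variables), object@nEventsUsed,
              if (object@converged) "converged" else
                paste0("NOT converged: ", object@diagnostics)))
  if (object@converged) {
    se <- sqrt(diag(object@vcov))
    df <- data.frame(beta = object@beta, HR = exp(object@beta), se = se)
    print(round(df, 4))
    cat(sprintf("log partial likelihood: %.4f (null %.4f)\n",
                object@logPartialLikelihood, object@nullLogLik))
  }
})

#' Prognostic index (Cox linear predictor)
#'
#' The per-patient risk score \eqn{\sum_j \beta_j x_j}; higher values
#' predict higher hazard.  Rankings are invariant under positive scaling of
#' the coefficients, which is all the downstream ROC machinery uses.
#'
#' @param fit A converged [CoxFit-class].
#' @param cohort Cohort containing the fit's variables (typically a test
#'   fold).
#' @return Named numeric vector of risk scores, one per patient.
#' @export
prognosticIndex <- function(fit, cohort) {
  if (!fit@converged) stop("cannot score with a non-converged fit: ",
                           fit@diagnostics)
  miss <- setdiff(fit@variables, rownames(cohort))
  if (length(miss))
    stop("variables missing from cohort: ", paste(miss, collapse = ", "))
  X <- t(assay(cohort, "scores")[fit@variables, , drop = FALSE])
  drop(X %*% fit@beta)
}

#' Univariate Cox analysis of every variable
#'
#' One single-variable Cox fit per modeling variable, reported as hazard
#' ratios with Wald 95% confidence intervals and p-values.  Degenerate
#' variables yield an `NA` row (with `converged = FALSE`) without aborting
#' the remaining fits.
#'
#' @param cohort A prepared [SurvivalCohort-class] (endpoint truncated, age
#'   binarized).
#' @param variables Variables to analyse, in output order (default: all).
#' @param level Confidence level (default 0.95).
#' @return data.frame with columns `variable`, `hazard_ratio`, `ci_low`,
#'   `ci_high`, `p_value`, `converged`.
#' @export
univariateAnalysis <- function(cohort, variables = variableNames(cohort),
                               level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  rows <- lapply(variables, function(v) {
    f <- fitCox(cohort, v)
    if (!f@converged)
      return(data.frame(variable = v, hazard_ratio = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        p_value = NA_real_, converged = FALSE))
    b <- f@beta[[1]]
    se <- sqrt(f@vcov[1, 1])
    data.frame(variable = v, hazard_ratio = exp(b),
               ci_low = exp(b - z * se), ci_high = exp(b + z * se),
               p_value = 2 * pnorm(-abs(b / se)), converged = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
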