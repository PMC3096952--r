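#' Likelihood-driven backward elimination
#'
#' Starting from the full variable set, repeatedly fits every
#' leave-one-variable-out Cox model on the training cohort and eliminates
#' the variable whose removal leaves the highest maximised partial
#' log-likelihood — the variable contributing least to the model likelihood
#' (equivalently, the smallest likelihood-ratio statistic).  Each eliminated
#' variable is moved to the top of the nested-variable list, so the returned
#' path lists variables from most to least important: the model of size m is
#' the first m entries.
#'
#' Non-convergent candidate fits are scored as likelihood `-Inf` and never
#' kept; exact likelihood ties are broken by removing the variable latest in
#' the declared variable order, making the path deterministic.  The module
#' uses no random numbers.
#'
#' @param train Training [SurvivalCohort-class] with >= 2 events.
#' @param variables Variables to start from (default: all), in declared
#'   order.
#' @return A [NestedModelPath-class].
#' @export
backwardEliminate <- function(train, variables = variableNames(train)) {
  if (!length(variables)) stop("'variables' must be non-empty")
  cd <- .cdFromMc(.mc(train, variables))
  new("NestedModelPath", orderedVariables = variables[.eliminateCore(cd)])
}

#' Evaluate the nested models of an elimination path
#'
#' For each size m = 1 ... p, trains the Cox model on the first m variables
#' of the path using the training cohort and scores its prognostic index on
#' the test cohort by ATD-AUCROC.  Non-convergent sizes are recorded with an
#' `NA` score.
#'
#' @param path A [NestedModelPath-class].
#' @param train,test Disjoint [SurvivalCohort-class] patient sets (the
#'   function does not enforce disjointness; cross-validation callers
#'   guarantee it).
#' @param ties Staircase tie convention.
#' @return data.frame with columns `size`, `score`, `converged`, plus the
#'   path as an attribute-free prefix rule (`variables[seq_len(size)]`).
#' @export
evaluateNestedModels <- function(path, train, test,
                                 ties = c("strict", "half")) {
  ties <- match.arg(ties)
  vars <- path@orderedVariables
  cd <- .cdFromMc(.mc(train, vars))
  res <- .evalNestedCore(cd, seq_along(vars), .mc(test, vars), ties)
  out <- data.frame(size = res$size, score = res$score,
                    train_loglik = res$trainLL, converged = res$converged)
  attr(out, "variables") <- vars
  out
}

#' Select the best reduced model from nested evaluations
#'
#' Returns the evaluated size with the highest ATD-AUCROC; ties are broken
#' toward the smaller size (parsimony).
#'
#' @param evaluations data.frame from [evaluateNestedModels()].
#' @return List with elements `size`, `score` and `variables` (the selected
#'   prefix of the path).
#' @export
selectReducedModel <- function(evaluations) {
  ok <- !is.na(evaluations$score)
  if (!any(ok)) stop("no scored entries to select from")
  ev <- evaluations[ok, , drop = FALSE]
  best <- max(ev$score)
  sz <- min(ev$size[ev$score == best])
  vars <- attr(evaluations, "variables")
  list(size = as.integer(sz), score = best,
       variables = if (!is.null(vars)) vars[seq_len(sz)] else NULL)
}

#' @describeIn backwardEliminate Display method for elimination paths.
#' @param object A NestedModelPath.
#' @export
setMethod("show", "NestedModelPath", function(object) {
  cat("NestedModelPath (most to least important):\n  ",
      paste(object@orderedVariables, collapse = " > "), "\n")
})
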