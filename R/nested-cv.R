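# round half away from zero (sizes are non-negative here)
.roundHalfUp <- function(x) floor(x + 0.5)

#' Performance-weighted aggregation of inner reduced models
#'
#' The two summary formulas of the inner loop, exposed for auditability.
#' `expectedModelSize` is the score-weighted average of the reduced-model
#' sizes, \eqn{\langle n\rangle = \sum_X h_X n_X / \sum_X h_X};
#' `variableStability` is the score-weighted fraction of reduced models
#' containing each variable,
#' \eqn{\langle v_m\rangle = \sum_X h_X U_X(v_m) / \sum_X h_X}.  With equal
#' weights they reduce to the arithmetic mean and the plain membership
#' frequency.  If every score is zero the weights are degenerate and
#' uniform weights are used instead.
#'
#' @param sizes Integer sizes of the reduced models.
#' @param scores Their ATD-AUCROC scores (the weights h).
#' @return `expectedModelSize`: a scalar in `[min(sizes), max(sizes)]`.
#' @export
expectedModelSize <- function(sizes, scores) {
  stopifnot(length(sizes) == length(scores), length(sizes) > 0)
  w <- if (sum(scores) > 0) scores else rep(1, length(scores))
  sum(w * sizes) / sum(w)
}

#' @rdname expectedModelSize
#' @param modelVariables List of character vectors, the variables of each
#'   reduced model.
#' @param variables The full variable set.
#' @return `variableStability`: named numeric in `[0, 1]` per variable.
#' @export
variableStability <- function(modelVariables, scores, variables) {
  stopifnot(length(modelVariables) == length(scores), length(scores) > 0)
  w <- if (sum(scores) > 0) scores else rep(1, length(scores))
  U <- matrix(
    vapply(variables, function(v)
      vapply(modelVariables, function(m) v %in% m, logical(1)),
      logical(length(modelVariables))),
    nrow = length(modelVariables), dimnames = list(NULL, variables))
  colSums(U * w) / sum(w)
}

# balanced, event-stratified fold labels: patients are shuffled within each
# stratum and fold labels dealt cyclically across the concatenated strata,
# so per-fold event counts AND total fold sizes each differ by at most one
.stratifiedFolds <- function(event, k) {
  f <- integer(length(event))
  ord <- c(sample(which(event == 1)), sample(which(event == 0)))
  f[ord] <- rep_len(seq_len(k), length(ord))
  f
}

#' Build a reproducible nested fold plan
#'
#' Partitions patients into `nOuter` non-overlapping, balanced outer folds,
#' stratified by the event indicator so every fold carries its share of
#' events ("balanced" subsets), and, for each outer iteration, partitions
#' the outer-training patients into `nInner` inner folds the same way.  All
#' assignments for all repeats are drawn from a single RNG stream seeded
#' once with `seed`, so the plan — and every downstream result — is
#' deterministic given the master seed.
#'
#' @param cohort A [SurvivalCohort-class].
#' @param nRepeats Number of repetitions of the outer cross-validation.
#' @param seed Integer master seed.
#' @param nOuter,nInner Fold counts (default 10 and 10).
#' @return A [FoldPlan-class].
#' @export
makeFoldPlan <- function(cohort, nRepeats = 100, seed = 1,
                         nOuter = 10, nInner = 10) {
  ev <- colData(cohort)$event
  n <- length(ev)
  if (sum(ev) < nOuter)
    stop(sprintf(paste0("only %d events for %d outer folds; every fold needs ",
                        "at least one event - use a larger cohort or fewer folds"),
                 sum(ev), nOuter))
  set.seed(as.integer(seed))
  assignments <- lapply(seq_len(nRepeats), function(r) {
    outer <- .stratifiedFolds(ev, nOuter)
    inner <- lapply(seq_len(nOuter), function(o) {
      v <- rep(NA_integer_, n)
      tr <- which(outer != o)
      v[tr] <- .stratifiedFolds(ev[tr], nInner)
      v
    })
    list(outer = outer, inner = inner)
  })
  new("FoldPlan", nRepeats = as.integer(nRepeats), nOuter = as.integer(nOuter),
      nInner = as.integer(nInner), seed = as.integer(seed),
      assignments = assignments)
}

#' @describeIn makeFoldPlan Display method.
#' @param object A FoldPlan.
#' @export
setMethod("show", "FoldPlan", function(object) {
  cat(sprintf("FoldPlan: %d repeats x %d outer folds (inner %d-fold), seed %d, %d patients\n",
              object@nRepeats, object@nOuter, object@nInner, object@seed,
              length(object@assignments[[1]]$outer)))
})

#' Run one inner cross-validation loop
#'
#' For each inner fold: backward-eliminates on the inner training set,
#' evaluates the nested models on the inner test fold, and selects the
#' reduced model with the highest inner ATD-AUCROC h.  From the collected
#' reduced models it computes the performance-weighted expected model size
#' \deqn{\langle n\rangle = \sum_X h_X n_X / \sum_X h_X}
#' and the per-variable inner stability score
#' \deqn{\langle v_m\rangle = \sum_X h_X U_X(v_m) / \sum_X h_X,}
#' where \eqn{U_X(v_m)} indicates membership of variable \eqn{v_m} in
#' reduced model X.  Unevaluable inner folds are skipped and recorded; the
#' summaries are computed over the remaining records.  If every inner score
#' is zero the weights are degenerate and unweighted means are used.
#'
#' @param outerTrain [SurvivalCohort-class] of the outer-training patients.
#' @param innerAssign Integer vector over `outerTrain` patients giving the
#'   inner fold of each (1 ... nInner).
#' @param variables Declared variable order.
#' @param ties Staircase tie convention.
#' @return An [InnerSummary-class].
#' @export
innerLoop <- function(outerTrain, innerAssign,
                      variables = variableNames(outerTrain),
                      ties = "strict") {
  res <- .innerCore(.mc(outerTrain, variables), innerAssign, variables, ties)
  records <- data.frame(fold = res$folds, size = res$sizes,
                        score = res$scores,
                        variables = I(res$varsList))
  new("InnerSummary", records = records, expectedSize = res$expectedSize,
      stability = res$stability, frequency = res$frequency,
      skippedFolds = res$skipped)
}

#' @describeIn innerLoop Display method.
#' @param object An InnerSummary.
#' @export
setMethod("show", "InnerSummary", function(object) {
  cat(sprintf("InnerSummary: %d reduced models, expected size <n> = %.2f\n",
              nrow(object@records), object@expectedSize))
  top <- sort(object@stability, decreasing = TRUE)
  cat("  most stable:", paste(sprintf("%s (%.2f)", names(top)[seq_len(min(5, length(top)))],
                                      top[seq_len(min(5, length(top)))]),
                              collapse = ", "), "\n")
})

#' Train and assess the reduced and full model of one outer iteration
#'
#' The reduced model contains the `round(<n>)` most stable variables of the
#' inner summary (rounding half away from zero, floored at 1; stability
#' ties broken by unweighted inner frequency, then declared variable
#' order), trained on the outer training set and scored (k) on the outer
#' test fold.  The full model uses all variables on the same split.  Both
#' are additionally scored on the training side as an overfitting
#' diagnostic.
#'
#' @param outerTrain,outerTest The outer split.
#' @param innerSummary An [InnerSummary-class] from [innerLoop()].
#' @param variables Declared variable order.
#' @param ties Staircase tie convention.
#' @return List with elements `reduced` and `full`, each a list
#'   `(variables, size, score, trainScore)`.
#' @export
outerIteration <- function(outerTrain, outerTest, innerSummary,
                           variables = variableNames(outerTrain),
                           ties = "strict") {
  inner <- list(expectedSize = innerSummary@expectedSize,
                stability = innerSummary@stability[variables],
                frequency = innerSummary@frequency[variables])
  res <- .outerCore(.mc(outerTrain, variables), .mc(outerTest, variables),
                    inner, variables, ties)
  res[c("reduced", "full")]
}

#' Run the full nested cross-validation procedure
#'
#' Orchestrates the whole pipeline: `nRepeats` times, patients are split
#' into `nOuter` event-stratified outer folds; inside each outer training
#' set an inner `nInner`-fold loop performs backward elimination, nested
#' model evaluation and reduced-model selection, yielding the expected
#' model size and variable stability scores; the reduced and full models
#' are then trained on the outer training set and assessed on the held-out
#' outer fold.  Selection therefore never sees outer test data.
#'
#' Aggregation across all repeats x outer folds produces the score
#' distributions, per-variable frequency-based stability (fraction of outer
#' reduced models containing the variable) and the k-weighted variant, and
#' a final model whose size is the rounded mean of the outer reduced sizes
#' and whose members are the top variables by frequency stability.
#'
#' Unevaluable folds are skipped and logged in the `skipped` slot; the run
#' aborts if more than 20% of outer folds are unevaluable.
#'
#' @param cohort A prepared [SurvivalCohort-class] (endpoint truncated, age
#'   binarized).
#' @param variables Modeling variable set (e.g. [variableSet()] output).
#' @param nRepeats Outer repetitions (default 100; scale down for quick
#'   runs).
#' @param seed Master seed; all randomness lives in the fold plan.
#' @param ties Staircase tie convention.
#' @param nOuter,nInner Fold counts.
#' @return A [CVSummary-class].
#' @export
runNestedCV <- function(cohort, variables = variableNames(cohort),
                        nRepeats = 100, seed = 1,
                        ties = c("strict", "half"),
                        nOuter = 10, nInner = 10) {
  ties <- match.arg(ties)
  plan <- makeFoldPlan(cohort, nRepeats, seed, nOuter, nInner)
  mcAll <- .mc(cohort, variables)
  outerRows <- list()
  innerRows <- list()
  skiplog <- list()
  for (r in seq_len(nRepeats)) {
    asg <- plan@assignments[[r]]
    for (o in seq_len(nOuter)) {
      trIdx <- which(asg$outer != o)
      res <- tryCatch({
        mcTrain <- .mcSub(mcAll, trIdx)
        mcTest <- .mcSub(mcAll, asg$outer == o)
        inner <- .innerCore(mcTrain, asg$inner[[o]][trIdx], variables, ties)
        it <- .outerCore(mcTrain, mcTest, inner, variables, ties)
        list(it = it, inner = inner)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        skiplog[[length(skiplog) + 1L]] <-
          data.frame(repeat_id = r, outer_fold = o,
                     reason = conditionMessage(res))
        next
      }
      inn <- res$inner
      innerRows[[length(innerRows) + 1L]] <- data.frame(
        repeat_id = r, outer_fold = o, inner_fold = inn$folds,
        size = inn$sizes, score = inn$scores,
        variables = I(inn$varsList),
        expected_size = inn$expectedSize)
      it <- res$it
      outerRows[[length(outerRows) + 1L]] <- data.frame(
        repeat_id = r, outer_fold = o,
        size = it$reduced$size, score = it$reduced$score,
        train_score = it$reduced$trainScore,
        full_score = it$full$score,
        full_train_score = it$full$trainScore,
        variables = I(list(it$reduced$variables)))
    }
  }
  skipped <- if (length(skiplog)) do.call(rbind, skiplog) else
    data.frame(repeat_id = integer(0), outer_fold = integer(0),
               reason = character(0))
  total <- nRepeats * nOuter
  if (nrow(skipped) > 0.2 * total)
    stop(sprintf("nested CV aborted: %d of %d outer folds unevaluable",
                 nrow(skipped), total))
  if (!length(outerRows))
    stop("nested CV produced no evaluable outer folds")
  outer <- do.call(rbind, outerRows)
  inner <- do.call(rbind, innerRows)

  k <- outer$score
  frequencyStability <- variableStability(outer$variables, rep(0, length(k)),
                                          variables)
  weightedStability <- variableStability(outer$variables, k, variables)

  p <- length(variables)
  finalSize <- min(p, max(1L, .roundHalfUp(mean(outer$size))))
  ord <- order(-frequencyStability, -weightedStability, seq_len(p))
  final <- variables[ord][seq_len(finalSize)]

  new("CVSummary",
      reducedScores = outer$score, fullScores = outer$full_score,
      reducedTrainScores = outer$train_score,
      fullTrainScores = outer$full_train_score,
      outerRecords = outer[, c("repeat_id", "outer_fold", "size", "score",
                               "train_score", "variables")],
      innerRecords = inner,
      frequencyStability = frequencyStability,
      weightedStability = weightedStability,
      finalModel = final, variables = variables,
      skipped = skipped, nRepeats = as.integer(nRepeats),
      seed = as.integer(seed))
}

#' Accessors for CVSummary results
#'
#' @name CVSummary-accessors
#' @rdname CVSummary-accessors
NULL

#' @rdname CVSummary-accessors
#' @export
setMethod("reducedScores", "CVSummary", function(object) object@reducedScores)

#' @rdname CVSummary-accessors
#' @export
setMethod("fullScores", "CVSummary", function(object) object@fullScores)

#' @rdname CVSummary-accessors
#' @export
setMethod("finalModel", "CVSummary", function(object) object@finalModel)

#' @rdname CVSummary-accessors
#' @export
setMethod("outerRecords", "CVSummary", function(object) object@outerRecords)

#' @rdname CVSummary-accessors
#' @export
setMethod("innerRecords", "CVSummary", function(object) object@innerRecords)

#' @rdname CVSummary-accessors
#' @export
setMethod("stabilityTable", "CVSummary", function(object) {
  data.frame(variable = object@variables,
             frequency_stability = as.numeric(object@frequencyStability),
             weighted_stability = as.numeric(object@weightedStability),
             in_final_model = object@variables %in% object@finalModel,
             row.names = NULL)
})

#' @describeIn runNestedCV Display method for CV summaries.
#' @param object A CVSummary.
#' @export
setMethod("show", "CVSummary", function(object) {
  cat(sprintf("CVSummary: %d repeats, %d evaluated outer folds (%d skipped)\n",
              object@nRepeats, length(object@reducedScores),
              nrow(object@skipped)))
  cat(sprintf("  mean outer ATD-AUCROC: reduced %.4f, full %.4f\n",
              mean(object@reducedScores), mean(object@fullScores)))
  cat(sprintf("  mean training-side:    reduced %.4f, full %.4f\n",
              mean(object@reducedTrainScores), mean(object@fullTrainScores)))
  cat(sprintf("  final model (%d variables): %s\n",
              length(object@finalModel),
              paste(object@finalModel, collapse = ", ")))
})
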