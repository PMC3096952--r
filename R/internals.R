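# Lightweight matrix-level representation used inside the cross-validation
# hot loops: the exported S4 API wraps these cores, which never touch
# SummarizedExperiment subsetting.
#
# mc: list(Xt = variables x patients matrix, time, event)
# cd: mc with patients sorted by increasing time (fitter contract) and
#     event renamed status

.mc <- function(cohort, variables = variableNames(cohort)) {
  miss <- setdiff(variables, rownames(cohort))
  if (length(miss))
    stop("variables not present in the cohort: ", paste(miss, collapse = ", "))
  list(Xt = assay(cohort, "scores")[variables, , drop = FALSE],
       time = as.numeric(colData(cohort)$time_years),
       event = as.numeric(colData(cohort)$event))
}

.mcSub <- function(mc, idx) {
  list(Xt = mc$Xt[, idx, drop = FALSE], time = mc$time[idx],
       event = mc$event[idx])
}

.cdFromMc <- function(mc) {
  o <- order(mc$time)
  list(Xt = mc$Xt[, o, drop = FALSE], time = mc$time[o],
       status = mc$event[o], variables = rownames(mc$Xt))
}

# Backward elimination on a prepared design; returns the nested path as
# variable indices (most important first).  Candidate fits only feed the
# likelihood ranking, so they use a slightly looser convergence tolerance
# than reported fits; differences between candidate likelihoods are orders
# of magnitude larger.
.eliminateCore <- function(cd, tol = 1e-7) {
  p <- nrow(cd$Xt)
  if (sum(cd$status) < 2)
    stop("at least 2 events are required in the training cohort")
  avail <- seq_len(p)
  nested <- integer(0)
  warm <- NULL
  step <- 0L
  while (length(avail) > 1) {
    step <- step + 1L
    lls <- numeric(length(avail))
    betas <- vector("list", length(avail))
    for (i in seq_along(avail)) {
      f <- .cox_fit_breslow(cd$Xt, cd$time, cd$status, avail[-i] - 1L,
                            if (!is.null(warm)) warm[-i] else NULL,
                            tol = tol, wantVcov = FALSE)
      if (isTRUE(f$converged)) {
        lls[i] <- f$loglik
        betas[[i]] <- f$beta
      } else lls[i] <- -Inf
    }
    if (all(!is.finite(lls)))
      stop(sprintf("backward elimination aborted at step %d: no leave-one-out fit converged",
                   step))
    best <- max(lls)
    cand <- which(lls >= best - 1e-9)
    di <- cand[which.max(avail[cand])]  # tie -> latest declared variable
    nested <- c(avail[di], nested)
    warm <- betas[[di]]
    avail <- avail[-di]
  }
  c(avail, nested)
}

.checkEvaluable <- function(time, event) {
  if (!any(event == 1) || !any(time[event == 1] < max(time)))
    stop("unevaluable test fold: no event time with both cases and controls")
}

# Train every prefix model of the path and score it on the test patients.
.evalNestedCore <- function(cd, pathIdx, mcTest, ties = "strict",
                            tol = 1e-9) {
  .checkEvaluable(mcTest$time, mcTest$event)
  half <- identical(ties, "half")
  p <- length(pathIdx)
  score <- rep(NA_real_, p)
  trainLL <- rep(NA_real_, p)
  conv <- logical(p)
  prevBeta <- NULL
  for (m in seq_len(p)) {
    ini <- if (m > 1L && conv[m - 1L]) c(prevBeta, 0) else NULL
    f <- .cox_fit_breslow(cd$Xt, cd$time, cd$status, pathIdx[seq_len(m)] - 1L,
                          ini, tol = tol, wantVcov = FALSE)
    conv[m] <- isTRUE(f$converged)
    if (conv[m]) {
      prevBeta <- f$beta
      trainLL[m] <- f$loglik
      sc <- drop(crossprod(mcTest$Xt[pathIdx[seq_len(m)], , drop = FALSE],
                           f$beta))
      score[m] <- .atd_value(sc, mcTest$time, mcTest$event, half)
    }
  }
  ll <- trainLL[conv]
  if (length(ll) > 1 && any(diff(ll) < -1e-6))
    warning("training log partial likelihood decreased along the nested path; check convergence")
  list(size = seq_len(p), score = score, trainLL = trainLL, converged = conv)
}

# One inner cross-validation loop on matrix-level data.
.innerCore <- function(mcOuter, innerAssign, variables, ties = "strict") {
  nInner <- max(innerAssign, na.rm = TRUE)
  folds <- integer(0)
  sizes <- integer(0)
  scores <- numeric(0)
  varsList <- list()
  skipped <- integer(0)
  for (f in seq_len(nInner)) {
    res <- tryCatch({
      trIdx <- which(innerAssign != f)
      teIdx <- which(innerAssign == f)
      cdTr <- .cdFromMc(.mcSub(mcOuter, trIdx))
      mcTe <- .mcSub(mcOuter, teIdx)
      pathIdx <- .eliminateCore(cdTr)
      ev <- .evalNestedCore(cdTr, pathIdx, mcTe, ties)
      ok <- !is.na(ev$score)
      if (!any(ok)) stop("no nested model converged")
      best <- max(ev$score[ok])
      sz <- min(ev$size[ok][ev$score[ok] == best])
      list(size = sz, score = best, vars = variables[pathIdx[seq_len(sz)]])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- c(skipped, f)
    } else {
      folds <- c(folds, f)
      sizes <- c(sizes, res$size)
      scores <- c(scores, res$score)
      varsList[[length(varsList) + 1L]] <- res$vars
    }
  }
  if (!length(folds)) stop("all inner folds were unevaluable")
  list(folds = folds, sizes = sizes, scores = scores, varsList = varsList,
       expectedSize = expectedModelSize(sizes, scores),
       stability = variableStability(varsList, scores, variables),
       frequency = variableStability(varsList, rep(0, length(scores)),
                                     variables),
       skipped = skipped)
}

# Outer iteration: reduced (top <n> most stable) and full model, trained on
# the outer training set, assessed on test and training side.
.outerCore <- function(mcTrain, mcTest, inner, variables, ties = "strict",
                       tol = 1e-9) {
  .checkEvaluable(mcTest$time, mcTest$event)
  half <- identical(ties, "half")
  p <- length(variables)
  nStar <- min(p, max(1L, .roundHalfUp(inner$expectedSize)))
  ord <- order(-inner$stability, -inner$frequency, seq_len(p))
  cdTr <- .cdFromMc(mcTrain)
  assess <- function(idx) {
    f <- .cox_fit_breslow(cdTr$Xt, cdTr$time, cdTr$status, idx - 1L, NULL,
                          tol = tol, wantVcov = FALSE)
    if (!isTRUE(f$converged))
      stop("outer model did not converge: ", f$diagnostics)
    sTr <- drop(crossprod(cdTr$Xt[idx, , drop = FALSE], f$beta))
    sTe <- drop(crossprod(mcTest$Xt[idx, , drop = FALSE], f$beta))
    list(variables = variables[idx], size = length(idx),
         score = .atd_value(sTe, mcTest$time, mcTest$event, half),
         trainScore = .atd_value(sTr, cdTr$time, cdTr$status, half))
  }
  list(reduced = assess(ord[seq_len(nStar)]), full = assess(seq_len(p)),
       nStar = nStar)
}
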