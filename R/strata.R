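#' Nottingham Prognostic Index
#'
#' The standard Galea formula
#' \deqn{NPI = 0.2 \times \mathrm{size\ (cm)} + \mathrm{grade} +
#'   \mathrm{node\ stage},}
#' with grade and node stage each in 1-3.  It reproduces the conventional
#' cut-points 3.4 (good) and 5.4 (poor); this package binarizes cohorts at
#' the midpoint 4.4 instead (see [splitByNPI()]).
#'
#' @param sizeCm Tumor size in cm (>= 0).
#' @param grade Nuclear grade, 1, 2 or 3.
#' @param nodeStage Nodal stage, 1, 2 or 3.
#' @return Numeric NPI value(s).
#' @examples
#' computeNPI(2, 2, 1)  # 3.4, the classical good/moderate boundary
#' @export
computeNPI <- function(sizeCm, grade, nodeStage) {
  if (any(!is.finite(sizeCm)) || any(sizeCm < 0))
    stop("'sizeCm' must be non-negative")
  if (!all(grade %in% 1:3)) stop("'grade' must be 1, 2 or 3")
  if (!all(nodeStage %in% 1:3)) stop("'nodeStage' must be 1, 2 or 3")
  0.2 * sizeCm + grade + nodeStage
}

#' Split a cohort at an NPI threshold
#'
#' Computes the NPI for every patient from the tumor-size and nuclear-grade
#' variables plus a nodal stage derived from the binary nodal-status
#' variable (negative -> stage 1, positive -> stage 2 by default, since a
#' binary status carries no positive-node count), and partitions the cohort
#' at the threshold.  Patients with NPI exactly at the threshold go to the
#' lower group ("NPI of 4.4 or less").
#'
#' @param cohort A [SurvivalCohort-class].
#' @param threshold NPI threshold (default 4.4, the midpoint of the
#'   standard 3.4/5.4 range).
#' @param sizeVar,gradeVar,nodeVar Variable names (defaults match
#'   [oncotypeCohortSpec()]).
#' @param nodeMap Length-2 numeric: node stage for negative and positive
#'   status.
#' @return `list(lower = , higher = )` of SurvivalCohorts partitioning the
#'   input.
#' @export
splitByNPI <- function(cohort, threshold = 4.4, sizeVar = "tumor_size",
                       gradeVar = "nuclear_grade", nodeVar = "nodal_status",
                       nodeMap = c(negative = 1, positive = 2)) {
  need <- c(sizeVar, gradeVar, nodeVar)
  miss <- setdiff(need, rownames(cohort))
  if (length(miss))
    stop("NPI components missing from cohort: ", paste(miss, collapse = ", "))
  sc <- assay(cohort, "scores")
  stage <- ifelse(sc[nodeVar, ] > 0, nodeMap[["positive"]],
                  nodeMap[["negative"]])
  npi <- computeNPI(sc[sizeVar, ], sc[gradeVar, ], stage)
  lower <- npi <= threshold
  list(lower = cohort[, lower], higher = cohort[, !lower])
}

#' Select the node-negative, hormone-receptor-positive subpopulation
#'
#' Keeps patients with negative nodal status whose tumors are ER positive,
#' PR positive or both, and removes the nodal-status variable from the
#' modeling set (it is constant in the subpopulation), so an 18-variable
#' panel leaves 17 modeling variables.
#'
#' @param cohort A [SurvivalCohort-class].
#' @param nodeVar,erVar,prVar Variable names.
#' @param positiveAbove Receptor scores strictly above this value count as
#'   positive (default 0, i.e. any non-zero IHC score).
#' @return The filtered SurvivalCohort without the nodal-status row.
#' @export
selectNodeNegativeHRPositive <- function(cohort, nodeVar = "nodal_status",
                                         erVar = "ER", prVar = "PR",
                                         positiveAbove = 0) {
  miss <- setdiff(c(nodeVar, erVar, prVar), rownames(cohort))
  if (length(miss))
    stop("required variables missing from cohort: ",
         paste(miss, collapse = ", "))
  sc <- assay(cohort, "scores")
  keep <- sc[nodeVar, ] == 0 &
    (sc[erVar, ] > positiveAbove | sc[prVar, ] > positiveAbove)
  out <- cohort[rownames(cohort) != nodeVar, keep]
  out
}

# Mann-Whitney U of sample a (ties credited 1/2)
.mwU <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Compare two score distributions (two-sided Mann-Whitney U)
#'
#' Used to compare ATD-AUCROC distributions of competing models across the
#' repeated cross-validation folds.  For small samples (total size at most
#' `exactMax`) the two-sided p-value is obtained by exhaustive enumeration
#' of all group assignments of the pooled values (handling ties exactly);
#' larger samples use the tie-corrected normal approximation.
#'
#' @param a,b Non-empty numeric score vectors.
#' @param exactMax Largest pooled size for exact enumeration (default 20).
#' @return A [ComparisonResult-class].
#' @examples
#' compareScoreDistributions(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
#' @export
compareScoreDistributions <- function(a, b, exactMax = 20) {
  if (!length(a) || !length(b)) stop("both score samples must be non-empty")
  if (anyNA(a) || anyNA(b)) stop("score samples must not contain NA")
  na <- length(a); nb <- length(b)
  u <- .mwU(a, b)
  mu <- na * nb / 2
  if (na + nb <= exactMax) {
    pool <- c(a, b)
    idx <- combn(na + nb, na)
    dev <- abs(apply(idx, 2, function(i) .mwU(pool[i], pool[-i])) - mu)
    p <- mean(dev >= abs(u - mu) - 1e-12)
    method <- "exact"
  } else {
    r <- rank(c(a, b))
    n <- na + nb
    tieTab <- table(r)
    sigma2 <- na * nb / 12 * ((n + 1) - sum(tieTab^3 - tieTab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal"
  }
  dir <- if (mean(a) > mean(b)) "a" else if (mean(a) < mean(b)) "b" else "tie"
  new("ComparisonResult", uStatistic = u, pValue = p,
      nA = as.integer(na), nB = as.integer(nb),
      direction = dir, method = method)
}

#' @describeIn compareScoreDistributions Display method.
#' @param object A ComparisonResult.
#' @export
setMethod("show", "ComparisonResult", function(object) {
  cat(sprintf("Mann-Whitney U = %.1f (n = %d vs %d), two-sided p = %.4g [%s]\n",
              object@uStatistic, object@nA, object@nB, object@pValue,
              object@method))
  if (object@direction != "tie")
    cat(sprintf("  larger mean: sample %s\n", object@direction))
})
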