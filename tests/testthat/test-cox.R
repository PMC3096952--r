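test_that("fitCox agrees with an independent generic-optimiser fit", {
  coh <- prepareEndpoint(binaryCohort(400, logHR = log(2), seed = 2))
  fit <- fitCox(coh, "grp")
  expect_true(fit@converged)
  o <- optimCoxFit(covariateMatrix(coh)[, "grp", drop = FALSE],
                   survTime(coh), survEvent(coh))
  expect_equal(fit@beta[["grp"]], o$beta, tolerance = 1e-6)
  expect_equal(fit@logPartialLikelihood, o$loglik, tolerance = 1e-8)
  # reported likelihood is recomputable from beta and the training data
  expect_equal(fit@logPartialLikelihood,
               breslowLogLik(fit@beta, covariateMatrix(coh)[, "grp",
                                                            drop = FALSE],
                             survTime(coh), survEvent(coh)),
               tolerance = 1e-10)
})

test_that("degenerate and invalid inputs are flagged, not fatal", {
  coh <- SurvivalCohort(cbind(const = rep(1, 30), ok = rnorm(30)),
                        time = rexp(30) + 0.1, event = rep(c(1, 0), 15))
  fit <- fitCox(coh, "const")
  expect_false(fit@converged)
  expect_match(fit@diagnostics, "degenerate")
  expect_error(fitCox(coh, character(0)), "non-empty")
  few <- SurvivalCohort(cbind(x = 1:4), time = 1:4, event = c(1, 0, 0, 0))
  expect_error(fitCox(few, "x"), "2 events")
  expect_error(fitCox(coh, "missing_var"), "not present")
})

test_that("partial likelihood is monotone under nested subsets", {
  set.seed(42)
  for (i in 1:5) {
    coh <- prepareEndpoint(generateCohort(
      oncotypeCohortSpec(nPatients = 120), seed = 100 + i))
    vars <- sample(variableSet("combined"), 4)
    lls <- vapply(seq_along(vars), function(m)
      fitCox(coh, vars[seq_len(m)])@logPartialLikelihood, numeric(1))
    expect_true(all(diff(lls) > -1e-8))
  }
})

test_that("prognosticIndex is the linear predictor and rank-invariant", {
  coh <- prepareEndpoint(generateCohort(oncotypeCohortSpec(nPatients = 150),
                                        seed = 8))
  fit <- fitCox(coh, c("AURKA", "nodal_status"))
  pi1 <- prognosticIndex(fit, coh)
  X <- covariateMatrix(coh)[, c("AURKA", "nodal_status")]
  expect_equal(unname(pi1), unname(drop(X %*% fit@beta)))
  # doubling the coefficients preserves the ranking
  fit2 <- fit
  fit2@beta <- 2 * fit@beta
  expect_identical(order(prognosticIndex(fit2, coh)), order(pi1))
  # zero coefficients give all-zero scores; single unit beta reproduces x
  fit0 <- fit
  fit0@beta[] <- 0
  expect_true(all(prognosticIndex(fit0, coh) == 0))
  expect_error(prognosticIndex(fit, coh[setdiff(rownames(coh), "AURKA"), ]),
               "missing")
})

test_that("univariate analysis produces coherent Wald intervals", {
  coh <- preparedCohort(oncotypeCohortSpec(nPatients = 500), seed = 3)
  ua <- univariateAnalysis(coh)
  expect_identical(nrow(ua), 18L)
  expect_identical(ua$variable, variableSet("combined"))
  ok <- ua$converged
  expect_true(all(ua$ci_low[ok] <= ua$hazard_ratio[ok]))
  expect_true(all(ua$hazard_ratio[ok] <= ua$ci_high[ok]))
  expect_true(all(ua$p_value[ok] > 0 & ua$p_value[ok] <= 1))
})

test_that("univariate Wald CI covers a true hazard ratio at ~95%", {
  hits <- 0
  nrep <- 60
  for (i in seq_len(nrep)) {
    coh <- prepareEndpoint(binaryCohort(300, logHR = log(2), seed = 400 + i))
    ua <- univariateAnalysis(coh, "grp")
    if (ua$ci_low[1] <= 2 && 2 <= ua$ci_high[1]) hits <- hits + 1
  }
  # binomial(60, .95): >= 51 hits keeps us within the plausible band
  expect_gte(hits, 51)
})
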