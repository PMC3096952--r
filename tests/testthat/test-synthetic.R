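test_that("generated cohorts respect marginal ranges and reproducibility", {
  spec <- oncotypeCohortSpec(nPatients = 300)
  coh <- generateCohort(spec, seed = 11)
  X <- covariateMatrix(coh)

  aqua <- c("AURKA", "BAG1", "BCL2", "BIRC5", "CCNB1", "CD68", "GRB7",
            "GSTM1", "KI67", "MMP11", "MYBL2")
  expect_true(all(X[, aqua] >= 0 & X[, aqua] <= 255))
  expect_true(all(X[, c("ER", "PR", "HER2")] %in% 0:3))
  expect_true(all(X[, "nodal_status"] %in% c(0, 1)))
  expect_true(all(X[, "nuclear_grade"] %in% 1:3))
  expect_true(all(X[, "age"] >= 24 & X[, "age"] <= 88))
  expect_true(all(survTime(coh) > 0))
  expect_true(all(survEvent(coh) %in% c(0, 1)))

  # same seed + same spec -> bit-identical cohort
  coh2 <- generateCohort(spec, seed = 11)
  expect_identical(covariateMatrix(coh), covariateMatrix(coh2))
  expect_identical(survTime(coh), survTime(coh2))
  expect_identical(survEvent(coh), survEvent(coh2))
  coh3 <- generateCohort(spec, seed = 12)
  expect_false(identical(survTime(coh), survTime(coh3)))
})

test_that("default panel spec matches its design targets", {
  spec <- oncotypeCohortSpec()
  expect_s4_class(spec, "CohortSpec")
  expect_identical(spec@nPatients, 638L)
  expect_identical(spec@horizonYears, 15)
  expect_length(spec@covariates, 18L)
  nm <- vapply(spec@covariates, function(s) s@name, character(1))
  expect_setequal(nm, variableSet("combined"))

  # tumor size mean ~2.9 cm with ~59% above 2 cm; age mean ~58
  big <- covariateMatrix(generateCohort(oncotypeCohortSpec(nPatients = 20000),
                                        seed = 5))
  expect_equal(mean(big[, "tumor_size"]), 2.9, tolerance = 0.05)
  expect_equal(mean(big[, "tumor_size"] > 2), 0.59, tolerance = 0.03)
  expect_equal(mean(big[, "age"]), 58, tolerance = 1)
  expect_equal(mean(big[, "nodal_status"]), 0.5, tolerance = 0.03)
  expect_equal(mean(big[, "ER"] > 0), 0.52, tolerance = 0.03)
  expect_equal(mean(big[, "HER2"] > 0), 0.14, tolerance = 0.02)
})

test_that("proportional-hazards outcome model recovers a known coefficient", {
  # one binary covariate with log HR = ln 2, exponential baseline
  coh <- prepareEndpoint(binaryCohort(5000, logHR = log(2), seed = 21))
  fit <- fitCox(coh, "grp")
  se <- sqrt(fit@vcov[1, 1])
  expect_true(fit@converged)
  expect_lt(abs(fit@beta[["grp"]] - log(2)), 3 * se)
})

test_that("null model gives covariate-independent survival", {
  betas <- setNames(rep(0, 18), variableSet("combined"))
  spec <- oncotypeCohortSpec(nPatients = 400, betas = betas)
  coh <- prepareEndpoint(generateCohort(spec, seed = 31))
  # univariate Wald p-values behave like nulls (no tiny p en masse)
  ua <- univariateAnalysis(coh, variableSet("combined"))
  expect_identical(nrow(ua), 18L)
  expect_lt(sum(ua$p_value < 0.05, na.rm = TRUE), 6)
})

test_that("event fraction decreases as censoring tightens", {
  base <- oncotypeCohortSpec(nPatients = 2000)
  fr <- vapply(c(30, 15, 6), function(cmax) {
    spec <- cohortSpec(nPatients = base@nPatients, covariates = base@covariates,
                       baseline = base@baseline,
                       censoring = list(type = "uniform", max = cmax),
                       horizonYears = 15)
    mean(survEvent(generateCohort(spec, seed = 7)))
  }, numeric(1))
  expect_true(all(diff(fr) < 0))
})

test_that("independent covariates show near-zero rank correlation", {
  coh <- generateCohort(oncotypeCohortSpec(nPatients = 2000), seed = 13)
  rc <- cor(covariateMatrix(coh), method = "spearman")
  expect_lt(mean(abs(rc[upper.tri(rc)])), 0.05)
})

test_that("a requested rank-correlation is imposed via the copula", {
  cm <- diag(18)
  cm[1, 2] <- cm[2, 1] <- 0.6
  coh <- generateCohort(oncotypeCohortSpec(nPatients = 4000, correlation = cm),
                        seed = 17)
  X <- covariateMatrix(coh)
  expect_equal(cor(X[, 1], X[, 2], method = "spearman"), 0.58,
               tolerance = 0.05)
  # marginals preserved
  expect_true(all(X[, 1] >= 0 & X[, 1] <= 255))
})

test_that("invalid specs are rejected with informative errors", {
  expect_error(cohortSpec(1, list(covariateSpec("x", "clinical_binary", p = 0.5))),
               "nPatients")
  expect_error(
    cohortSpec(10, list(covariateSpec("x", "clinical_binary", p = 0.5)),
               horizonYears = -1),
    "horizonYears")
  expect_error(covariateSpec("x", "ihc_marker", probs = c(0.5, 0.4)),
               "sum to 1")
  expect_error(covariateSpec("x", "nonsense"), "kind")
  bad <- matrix(c(1, 0.9, 0.2, 1), 2, 2)  # asymmetric
  expect_error(
    cohortSpec(10, list(covariateSpec("a", "clinical_binary", p = 0.5),
                        covariateSpec("b", "clinical_binary", p = 0.5)),
               correlation = bad),
    "symmetric")
})
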