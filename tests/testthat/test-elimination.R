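test_that("single variable yields the trivial path", {
  coh <- prepareEndpoint(binaryCohort(100, seed = 5))
  p <- backwardEliminate(coh, "grp")
  expect_identical(p@orderedVariables, "grp")
})

test_that("null variables are eliminated before a strong signal variable", {
  # A carries HR 2.5, B is null; B should fall first nearly always
  spec <- cohortSpec(
    nPatients = 600,
    covariates = list(
      covariateSpec("A", "clinical_binary", p = 0.5, trueBeta = log(2.5)),
      covariateSpec("B", "clinical_binary", p = 0.5, trueBeta = 0)),
    baseline = list(family = "exponential", rate = 0.05),
    horizonYears = 15)
  firstOut <- vapply(1:40, function(i) {
    coh <- prepareEndpoint(generateCohort(spec, seed = 1000 + i))
    path <- backwardEliminate(coh)
    path@orderedVariables[2]  # bottom of a 2-variable path = eliminated
  }, character(1))
  expect_gte(mean(firstOut == "B"), 0.95)
})

test_that("each elimination step keeps the highest-likelihood reduced model", {
  coh <- preparedCohort(oncotypeCohortSpec(nPatients = 250), seed = 9)
  vars <- variableSet("clinical_only")
  path <- backwardEliminate(coh, vars)
  expect_setequal(path@orderedVariables, vars)
  # the kept model at each step must beat every alternative single removal
  remaining <- vars
  for (step in seq_len(length(vars) - 1)) {
    eliminated <- path@orderedVariables[length(vars) - step + 1]
    keptLL <- fitCox(coh, setdiff(remaining, eliminated))@logPartialLikelihood
    for (alt in setdiff(remaining, eliminated)) {
      altLL <- fitCox(coh, setdiff(remaining, alt))@logPartialLikelihood
      expect_gte(keptLL, altLL - 1e-6)
    }
    remaining <- setdiff(remaining, eliminated)
  }
})

test_that("elimination is deterministic and RNG-free", {
  coh <- preparedCohort(oncotypeCohortSpec(nPatients = 200), seed = 4)
  p1 <- backwardEliminate(coh, variableSet("clinical_only"))
  set.seed(999)  # must not matter
  p2 <- backwardEliminate(coh, variableSet("clinical_only"))
  expect_identical(p1@orderedVariables, p2@orderedVariables)
})

test_that("evaluateNestedModels scores every prefix on the test fold", {
  coh <- preparedCohort(oncotypeCohortSpec(nPatients = 300), seed = 14)
  tr <- coh[, 1:240]
  te <- coh[, 241:300]
  vars <- variableSet("clinical_only")
  path <- backwardEliminate(tr, vars)
  ev <- evaluateNestedModels(path, tr, te)
  expect_identical(nrow(ev), length(vars))
  expect_identical(ev$size, seq_along(vars))
  expect_true(all(ev$score[ev$converged] >= 0 & ev$score[ev$converged] <= 1))
  # training likelihood non-decreasing along the nested path
  ll <- ev$train_loglik[ev$converged]
  expect_true(all(diff(ll) > -1e-6))
  # deliberate-leak consistency: test == train must reproduce training-side
  evLeak <- evaluateNestedModels(path, tr, tr)
  fit <- fitCox(tr, path@orderedVariables)
  expect_equal(evLeak$score[length(vars)],
               atdAUC(prognosticIndex(fit, tr), survTime(tr),
                      survEvent(tr))@value)
})

test_that("selectReducedModel takes the max score with ties to parsimony", {
  ev <- data.frame(size = 1:3, score = c(0.6, 0.7, 0.65),
                   train_loglik = NA, converged = TRUE)
  attr(ev, "variables") <- c("a", "b", "c")
  sel <- selectReducedModel(ev)
  expect_identical(sel$size, 2L)
  expect_identical(sel$variables, c("a", "b"))
  tie <- data.frame(size = c(2, 5), score = c(0.7, 0.7), converged = TRUE)
  attr(tie, "variables") <- letters[1:5]
  expect_identical(selectReducedModel(tie)$size, 2L)
  one <- data.frame(size = 4, score = 0.8, converged = TRUE)
  expect_identical(selectReducedModel(one)$size, 4L)
  empty <- data.frame(size = 1, score = NA_real_, converged = FALSE)
  expect_error(selectReducedModel(empty), "no scored")
})
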