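# Independent oracles used to validate the package's own implementations.
# They deliberately take the dumbest correct route (triple loops, generic
# optimisation) and share no code with the implementation paths.

# Brute-force average time-dependent AUCROC: enumerate every death event
# time and every case-control pair.
bruteATD <- function(scores, time, event, ties = "strict") {
  evTimes <- time[event == 1]
  aucs <- numeric(0)
  wts <- integer(0)
  for (t in sort(unique(evTimes))) {
    cases <- which(time <= t & event == 1)
    controls <- which(time > t)
    if (length(cases) && length(controls)) {
      credit <- 0
      for (i in cases) {
        for (j in controls) {
          if (scores[i] > scores[j]) credit <- credit + 1
          else if (ties == "half" && scores[i] == scores[j])
            credit <- credit + 0.5
        }
      }
      aucs <- c(aucs, credit / (length(cases) * length(controls)))
      wts <- c(wts, sum(evTimes == t))
    }
  }
  if (!length(aucs)) stop("unevaluable")
  sum(aucs * wts) / sum(wts)
}

# Breslow partial log-likelihood written directly from its definition, and
# a generic-optimiser Cox fit based on it (independent of the package's
# Newton-Raphson path).
breslowLogLik <- function(beta, X, time, event) {
  lp <- drop(X %*% beta)
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    dead <- which(time == t & event == 1)
    risk <- which(time >= t)
    ll <- ll + sum(lp[dead]) - length(dead) * log(sum(exp(lp[risk])))
  }
  ll
}

optimCoxFit <- function(X, time, event) {
  fit <- optim(rep(0, ncol(X)),
               function(b) -breslowLogLik(b, X, time, event),
               method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  list(beta = fit$par, loglik = -fit$value)
}

# random small survival instance with ties in both scores and times
randomInstance <- function(n, scoreLevels = 6, timeLevels = 8) {
  list(scores = sample(seq_len(scoreLevels), n, replace = TRUE) + 0,
       time = sample(seq_len(timeLevels), n, replace = TRUE) + 0,
       event = rbinom(n, 1, 0.5) + 0)
}

evaluableInstance <- function(inst) {
  any(inst$event == 1) && any(inst$time[inst$event == 1] < max(inst$time))
}

# a small cohort with one binary covariate carrying a known hazard ratio
binaryCohort <- function(n, logHR = log(2), rate = 0.1, seed = 1) {
  spec <- cohortSpec(
    nPatients = n,
    covariates = list(
      covariateSpec("grp", "clinical_binary", p = 0.5, trueBeta = logHR)),
    baseline = list(family = "exponential", rate = rate),
    horizonYears = 15)
  generateCohort(spec, seed = seed)
}

# the acceptance-study design: the 18-variable panel with exactly four
# signal variables (two markers, two clinical) at HR ~ 2 per SD of the raw
# score, baseline calibrated to ~40% observed disease deaths at 15 years
fourSignalSpec <- function(nPatients = 600) {
  betas <- setNames(rep(0, 18), variableSet("combined"))
  betas[c("AURKA", "MYBL2", "nodal_status", "tumor_size")] <-
    c(0.0220, 0.0223, 1.3863, 0.3255)
  oncotypeCohortSpec(nPatients = nPatients, betas = betas,
                     baselineRate = 0.0022)
}

fourSignalVariables <- c("AURKA", "MYBL2", "nodal_status", "tumor_size")

preparedCohort <- function(spec, seed) {
  binarizeAge(prepareEndpoint(generateCohort(spec, seed = seed)))
}
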