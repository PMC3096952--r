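---
title: "Composite prognostic models under nested cross-validation: methods and design choices"
author: "prognest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite prognostic models under nested cross-validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prognest)
```

## The problem

Multi-marker prognostic assays for early breast cancer ask whether a panel
of tumor protein measurements, combined with routine clinico-pathological
information, predicts disease-specific survival well enough to guide
adjuvant therapy decisions. Two statistical traps dominate this setting:
optimistic evaluation (reusing patients for both selection and assessment)
and unstable variable selection (small panels chosen on one data split
rarely reappear on another). `prognest` implements a pipeline that
addresses both: a Cox proportional-hazards prognostic index over raw
covariates, a conservative time-dependent discrimination statistic, and
stability-based backward elimination run entirely inside a nested
cross-validation so that model-size selection never touches the data used
to report performance.

## The model

For patient $i$ with covariate vector $x_i$ (marker scores and clinical
variables on their raw scales), the hazard is modeled as
$h(t \mid x_i) = h_0(t)\exp(\beta^\top x_i)$. The prognostic index is the
linear predictor $\eta_i = \beta^\top x_i$; only its ranking enters the
evaluation, so the baseline hazard never needs to be estimated.
Coefficients are maximum partial-likelihood estimates with the Breslow
approximation for tied event times, computed by the package's own
Newton-Raphson solver (`src/cox_breslow.cpp`). Covariates are used
unstandardized throughout: marker distributions in this field are strongly
skewed (most patients score low), and rank-based evaluation of the linear
predictor makes standardization unnecessary; the test suite cross-checks
the solver against `survival::coxph(ties = "breslow")` to $10^{-6}$ and
against direct optimization of a hand-written Breslow likelihood.

Tied event times are handled by Breslow rather than Efron: the elimination
procedure compares thousands of leave-one-out likelihoods, and Breslow is
the most widely reproduced convention with the simplest likelihood
ordering; any external comparison should configure Efron-default software
accordingly.

## The evaluation statistic: ATD-AUCROC

Discrimination is measured by the average time-dependent AUCROC. At the
time $t$ of each death event in a test set, patients are divided into
*cases* — those already dead of disease ($T_i \le t$, $\delta_i = 1$;
cumulative) — and *controls* — those still under observation beyond $t$
($T_i > t$; dynamic). Patients censored at or before $t$ carry no
information about status at $t$ and are excluded at that time point. The
ROC curve at $t$ is the empirical staircase (step function), whose area is
the fraction of case-control pairs with a *strictly* larger case score:

$$\mathrm{AUC}(t) \;=\; \frac{1}{|C_t|\,|D_t|} \sum_{i \in D_t} \sum_{j \in C_t}
  \mathbf{1}\{\eta_i > \eta_j\}.$$

The ATD-AUCROC is the unweighted mean of $\mathrm{AUC}(t)$ over all death
events (events sharing a time each contribute one term; the final event
time, where no controls remain, is recorded but excluded because the AUC
is undefined there).

Three conventions deserve explicit statement:

* **Ties score zero.** Crediting tied pairs $1/2$ is exactly the
  trapezoidal correction the staircase curve is chosen to avoid; the
  strict-inequality convention is conservative. The half-credit variant
  remains available (`ties = "half"`) for sensitivity analysis, and with
  it an uninformative constant score sits at 0.5 rather than 0.
* **Cumulative cases, dynamic controls.** "Evaluating at each event time"
  is read in the cumulative/dynamic sense standard for survival
  discrimination; it uses every test patient consistently at every time.
* **Event multiplicity.** Averaging is over events, not distinct times, so
  a time with $d$ deaths contributes $d$ identical terms.

The statistic is invariant under any strictly increasing transform of the
scores, equals a brute-force enumeration over all events and pairs exactly
on every instance the suite generates, and maps to $1 - v$ under score
reversal when no ties occur. No inverse-probability-of-censoring weighting
is applied; censoring is assumed independent of the covariates, which the
synthetic generator enforces and which real cohorts satisfy only
approximately.

## Backward elimination and the nested model path

Given a training set and $p$ variables, the elimination loop repeatedly
fits all single-removal Cox models and discards the variable whose removal
leaves the highest maximized partial log-likelihood — the variable
contributing least, equivalently the smallest likelihood-ratio statistic.
Each discarded variable is pushed onto the top of a nested-variable list,
so the final list orders variables from most to least important and the
model of size $m$ is its first $m$ entries. Two determinism rules apply:
exact likelihood ties (within $10^{-9}$) are resolved by removing the
variable latest in the declared variable order, and candidate fits that
fail to converge are treated as likelihood $-\infty$, so separation
artifacts can never steer the path. The module is RNG-free: the same
training data always yield the same path.

## The nested cross-validation

One run consists of `nRepeats` repetitions of:

1. Partition patients into 10 outer folds, stratified by the event
   indicator ("balanced" folds). Stratification is what guarantees every
   fold is evaluable; fold sizes and per-fold event counts each differ by
   at most one.
2. For each outer fold: split the outer-training patients into 10 inner
   folds. On each inner fold, eliminate backwards on the inner training
   set, score every nested model size on the inner test fold
   (ATD-AUCROC $h$), and keep the best size (ties toward the smaller
   model — parsimony is the procedure's point).
3. Aggregate the 10 inner reduced models into the expected model size
   $\langle n\rangle = \sum_X h_X n_X / \sum_X h_X$ and per-variable
   stability scores
   $\langle v_m\rangle = \sum_X h_X U_X(v_m) / \sum_X h_X$, where
   $U_X(v_m)$ indicates membership in reduced model $X$.
4. Train the reduced model — the $\operatorname{round}(\langle n\rangle)$
   most stable variables — and the full model on the outer training set,
   and score both on the held-out outer fold ($k$), plus on the training
   side as an overfitting diagnostic.

Numerical conventions chosen where the procedure itself is silent:

* $\langle n\rangle$ is rounded half away from zero and floored at 1 (a
  model must contain an integer, positive number of variables).
* Stability ties at the $\langle n\rangle$-th rank are broken by the
  unweighted inner membership frequency, then by declared variable order.
  (The primary ranking is already the $h$-weighted score, so a second
  weighted criterion would be circular.)
* If every inner score is zero the weights are degenerate and unweighted
  means are used.
* An unevaluable fold (no event time with both cases and controls, or a
  non-convergent outer model) is skipped and logged; the run aborts only
  if more than 20% of outer folds are lost.

Across all repeats, two cross-run stability summaries are reported: the
*frequency* stability (fraction of outer reduced models containing each
variable) and the $k$-weighted variant. The final aggregated model takes
its size from the rounded mean of the outer reduced sizes and its members
from the top variables by frequency stability — frequency, not the
weighted variant, because the across-run summary should not double-count
performance that already drove the within-run selection; the weighted
variant is reported alongside. Whether a final model should use the mean,
mode, or a representative run of the size distribution is genuinely open;
the mean-then-round choice is the package's, and the full size
distribution is always written by `writeReports()` so the reader can judge.

**RNG policy.** All randomness lives in the fold plan: `makeFoldPlan()`
seeds one RNG stream with the master seed and draws every repeat's outer
and inner assignments from it in order. Everything downstream is
deterministic, so a `CVSummary` is reproducible bit-for-bit from
(cohort, variable set, `nRepeats`, seed).

## Stratified analyses

The Nottingham Prognostic Index is computed by the standard Galea formula
$\mathrm{NPI} = 0.2\times\text{size (cm)} + \text{grade} +
\text{node stage}$ — the only standard formula consistent with the
conventional 3.4/5.4 cut-points. Because the modeling panel carries only a
binary nodal status, node stage defaults to negative $\to$ 1, positive
$\to$ 2 (configurable); cohorts with a positive-node count can supply the
true stage. Cohorts are binarized at NPI 4.4 — the midpoint of the
standard range, chosen over the 3.4/5.4 three-group split for sample-size
reasons — with boundary patients (exactly 4.4) in the lower group. The
node-negative, hormone-receptor-positive subpopulation keeps patients with
negative nodal status and ER and/or PR positive (any non-zero IHC score by
default) and drops nodal status from the modeling set, leaving 17 of 18
variables.

Score distributions of competing models are compared with two-sided
Mann-Whitney U tests: exact enumeration of all group assignments (ties
handled exactly) when the pooled sample is small, and the tie-corrected
normal approximation otherwise.

## The synthetic cohort generator

No patient-level data ship with the package; `generateCohort()` produces
cohorts with the statistical structure the analysis assumes, and
`oncotypeCohortSpec()` configures a realistic default: 638 patients,
15-year follow-up, and an 18-variable panel (11 continuous
immunofluorescence marker scores, three ordinal IHC receptor scores, four
clinico-pathological variables).

* **Marker scores** are clipped log-normal on the 0-255 intensity scale
  (`meanlog = 3`, `sdlog = 0.9`), giving the "predominantly low" skew
  characteristic of quantitative immunofluorescence.
* **IHC scores** are categorical on 0-3 with the point mass at zero sized
  so that roughly 52% (ER), 46% (PR) and 14% (HER2) of patients are
  positive.
* **Clinical variables**: binary nodal status at 50%; log-normal tumor
  size with mean 2.9 cm and 59% above 2 cm; nuclear grade 1-3 at roughly
  20/52/28%; age normal with mean 58, clipped to 24-88 years.
* **Effects**: default log hazard ratios give univariate effects
  realistic for such a cohort — nodal status HR $\approx$ 2.4, tumor size
  $\approx$ 1.13 per cm, grade $\approx$ 1.3 per level, ER $\approx$ 0.81
  per IHC point, AURKA $\approx$ 1.013 per intensity unit — with several
  markers essentially null, so selection has both signal and noise to
  work with.
* **Outcome**: exponential (or Weibull) baseline; the default rate
  0.013/year yields roughly 35-40% observed disease deaths within the
  horizon. Censoring is uniform on $(0, 2\times\text{horizon}]$ plus the
  administrative cut at the horizon, independent of covariates by
  construction. The observed time is the minimum of event, censoring and
  horizon; an event falling exactly on the horizon is kept as an event.
* Optional rank correlation among covariates is imposed through a
  Gaussian copula, preserving every marginal family.

What the generator does *not* emulate: measurement error and batch effects
in staining, informative censoring, non-proportional hazards, missing
data patterns, or treatment effects. Tests passing on these cohorts show
that the machinery is correct under its own assumptions — not that those
assumptions hold in any particular clinical cohort.

## Problem sizes used by the test suite

The suite exercises the full pipeline at sizes chosen to finish on a
single CPU in minutes while leaving the statistical questions answerable:
metric-oracle checks on 200 random instances of up to 30 patients; Cox
oracle agreement on 100 cohorts of 2,000 patients; selection-recovery on
20 independent 600-patient cohorts (18 variables, four carrying HR
$\approx$ 2 per SD, ~40% events) each analysed with 5 repeats of the
10-outer/10-inner design; block-structure comparison at 10 repeats; and
null calibration averaged over 16 independent pure-noise cohorts of 600
patients (within one finite cohort, cross-validation estimates that
cohort's own chance association, with per-cohort spread around 0.04 at
this size — a property worth knowing when reading any single-cohort
cross-validated AUC). The acceptance script runs the
638-patient default at 10 repeats. These are the package's choices of
scale; the procedure itself has no intrinsic limit below memory.

## Known limitations

* The reported stability scores are conditional on the backward-elimination
  path; forward or best-subset searches could rank correlated variables
  differently (deliberately out of scope).
* The ATD-AUCROC excludes censored-before-$t$ patients rather than
  reweighting survivors; under heavy, covariate-dependent censoring a
  weighted (IPCW) variant would be less biased.
* With strongly correlated variables, stability mass spreads across the
  correlated set and the final model membership can alternate between
  near-equivalent panels; the frequency table written by `writeReports()`
  is the honest summary in that situation.
* Exact Mann-Whitney enumeration is limited to small pooled samples
  (default 20); cross-validated score distributions are far larger and
  always use the normal approximation, whose independence assumption is
  itself optimistic for overlapping training sets — p-values between fold
  score distributions should be read as descriptive, a caveat shared by
  the procedure this package implements.
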