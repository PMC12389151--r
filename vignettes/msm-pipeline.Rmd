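---
title: "Marginal structural models for a four-level drinking exposure and repeated depression screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marginal structural models for a four-level drinking exposure and repeated depression screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimation problem

Older adults report their alcohol consumption annually; each report is
classified into one of four categories — abstainer, occasional, moderate,
above-guideline — from drinking frequency (days/week), average standard
drinks per drinking day, and a heavy-episodic-drinking flag, with
sex-specific weekly-volume limits (7 drinks for women, 14 for men; a
volume exactly at the limit counts as moderate so the rule is a
partition). Depression is screened with the CES-D-10 (items 0–3,
positive-mood items 5 and 8 reverse-coded, total 0–30), dichotomised at
8 (primary) or 10 (sensitivity). Observational contrasts of depression
risk across drinking categories are confounded by health and social
factors that are themselves affected by earlier drinking (a classic
time-varying-confounding feedback), and annual dropout is informative.
Standard regression adjustment is biased in this setting; the package
instead estimates a *marginal structural model* (MSM): the
population-average odds of probable depression one year after exposure,
as a function of the current exposure category,

$$\operatorname{logit} \Pr(Y_{t+1}^{\bar a} = 1) = \beta_0 + \beta_{A}[a_t],$$

with moderate consumption as the reference. Estimation reweights each
observation by the product of an inverse-probability-of-treatment weight
(IPTW, from a multinomial model of the category given the previous
category, the time-updated confounders and baseline covariates) and an
inverse-probability-of-censoring weight (IPCW, from pooled logistic
models of remaining under follow-up). In the reweighted
pseudo-population the exposure is independent of the measured
confounders at every wave, so a weighted logistic fit of the outcome on
the current category — with independence working correlation and a
cluster-robust (sandwich) variance over participants — estimates the
causal contrasts under the usual identification assumptions (no
unmeasured confounding, positivity, consistency).

Intention-to-treat (`run_itt()`) classifies everyone by the baseline
category regardless of later change and uses point-treatment baseline
weights; per-protocol (`run_pp()`, the primary analysis) uses the
annually time-updated category with sequential weights. A one-wave lag
between exposure and outcome (`lag_exposure()`) fixes the temporal
ordering; outcome waves lost to dropout are flagged and enter through
the censoring weights of the retained rows rather than being silently
discarded.

## Weighting choices

**Stabilisation.** `compute_iptw()` supports unstabilised weights
(`1/P(A_t \mid \cdot)`), marginal-numerator stabilised weights, and
history-numerator stabilised weights (numerator
`P(A_t \mid A_{t-1}, t)` estimated by per-wave transition frequencies).
The pipeline defaults to stabilised history-numerator cumulative
weights. The reason is variance: the exposure is highly persistent
(per-wave repetition 55–90% by category), so the unstabilised cumulative
product has expectation $4^{t+1}$ and a heavy tail — on the default
six-wave cohort its maximum reaches the millions and no reasonable
trimming rule rescues balance. The history numerator divides out the
predictable persistence component, leaving per-wave factors near 1.

**Trimming.** `combine_and_trim()` implements the percentile rule:
observations outside the 2nd–98th percentile band of the combined
weight are excluded (or winsorised with `mode = "cap"`), with
nearest-rank percentiles computed once on the pooled analysis rows;
with $n$ rows exactly `floor(0.02 n)` fall outside each tail, trimming
at (0, 100) is the identity, and a degenerate all-equal distribution
excludes nothing. The *pipeline* default, however, is no trimming:
in repeated simulation at $n = 2{,}000$ over four waves the 2/98
exclusion rule biased the stabilised-weight estimator upward by
0.07–0.12 on the log-OR scale (tail exclusion is selection on a
function of the confounders), capping by about 0.04, while untrimmed
stabilised weights were essentially unbiased with 95–96% CI coverage.
Percentile exclusion is the natural companion of *unstabilised*
weights, and both remain available for that configuration.

**Censoring models.** Retention is modelled among participants under
follow-up at the previous wave, pooled across waves with wave
indicators. The default predictor set is the previous wave's
time-updated covariates plus the exposure category
(`censoring_covariates = "time_updated"`), which is the correctly
specified choice when dropout depends on evolving health;
`"baseline"` restricts to baseline values. Waves without any dropout
contribute retention probability 1 and are excluded from the fit.

**Working correlation.** Only independence is offered. With
inverse-probability weights, non-independence working correlations can
make the estimating equations inconsistent for the marginal parameters,
so the conventional MSM practice of an independence working model with
a cluster-robust sandwich variance is hard-wired.

**Balance.** `balance_report()` computes standardized mean differences
per covariate for each category-vs-moderate contrast, before and after
weighting, flagging $|SMD| \ge 0.10$. In the pipeline the SMDs are
computed within exposure wave and combined by stratum size: the
category mix drifts across waves (occasional drinkers migrate into
abstention), and pooling waves would confound that drift with genuine
covariate imbalance — under perfectly specified weights the pooled SMD
still exceeds 0.10 while every per-wave SMD is near zero.

## The synthetic cohort and its oracle

`simulate_cohort()` generates the study conditions the package targets:
about 16,500 adults aged 70+ (age truncated normal 75.1 ± 4.6 years,
54% female), baseline category proportions 26.9 / 21.2 / 32.6 / 19.3%
(abstainer / occasional / moderate / above-guideline), six annual
waves, ~9% per-wave prevalence of probable depression, ~6% per-wave
informative dropout, and a J-shaped conditional effect (default
conditional ORs 1.18 / 1.115 / 1 / 1.16 versus moderate, chosen so the
induced marginal ORs sit near 1.17 / 1.11 / 1 / 1.15).

Confounding is carried by a scalar latent health-burden index $L$:

* at baseline, $A_0$ is drawn at the target proportions and
  $(L_0, \text{sex}) \mid A_0$ from category-specific conditionals
  ($L_0 \sim N(\mu_a, 1)$ with $\mu$ spread 0.6 between abstainers and
  moderates; female share per category 66.8 / 62.4 / 33.2 / 62.1%).
  By Bayes' rule the implied $P(A_0 \mid L_0, \text{sex})$ is exactly a
  multinomial logit, so the fitted propensity model is correctly
  specified while the baseline proportions are matched exactly in
  expectation;
* at follow-up waves, $L_t = 0.7 L_{t-1} + \gamma[A_{t-1}] + N(0, 0.71)$
  and the next category follows a multinomial logit in $L_t$, sex and
  the previous category, with own-category persistence boosts
  calibrated to per-wave repetition targets (0.90 / 0.55 / 0.80 / 0.70,
  highest for abstainers, lowest for occasional drinkers, matching the
  adherence ordering of the emulated cohort). The realised follow-up
  drift — occasional drinkers migrating into abstention — mirrors the
  pattern described for ageing cohorts;
* dropout at wave $t$ is Bernoulli in $L_{t-1}$ and $A_{t-1}$
  (informative censoring); once censored, always censored;
* the outcome at wave $t$ is Bernoulli in $A_{t-1}$, $L_{t-1}$, age and
  sex — the one-year exposure–outcome lag is built into the generating
  process. CES-D-10 totals are then drawn consistently with the binary
  state (55% of cases at or above 10, giving the cutoff-10 sensitivity
  analysis something to bite on; the implied mean total is about 3).

The exposure→confounder feedback $\gamma = (0.02, 0, -0.01, 0.02)$ is
deliberately small. It keeps the "confounder affected by prior
exposure" structure that motivates MSMs while making the single-term
marginal model $\beta_A[a_t]$ a near-exact summary of the always-treated
regimes the oracle evaluates; with large feedback the two estimands
genuinely diverge and no marginal-model estimator could match the
oracle. Confounding strength comes instead from the baseline
distribution of $L$ and its AR(1) persistence — enough that the naive
fit is several robust standard errors from the truth.

`true_marginal_effects()` is the counterfactual oracle: it simulates
each arm with every participant held at one category at every wave,
censoring disabled, using baseline covariates drawn from the natural
(uninterverned) distribution and covariate noise shared across arms.
It averages the conditional outcome *probabilities* rather than
Bernoulli draws (Rao-Blackwellisation), so the Monte-Carlo error of the
log-OR contrasts is far below 0.01 already at the default
`n_mc = 20,000`, and it reports a delta-method MC standard error that
accounts for the between-arm covariance induced by the shared draws.
The oracle exists because the odds ratio is noncollapsible: the
marginal OR differs from the conditional coefficient even without
confounding, so the truth must be computed, not read off the config.

## What the simulations do and do not show

The generator exercises exactly the structures the estimator claims to
handle: four-level persistent exposure, a measured time-varying
confounder with treatment feedback, informative monotone dropout, a
binary repeated outcome with known J-shaped causal pattern, former
drinkers flagged within baseline abstainers (25%, for the sick-quitter
sensitivity analysis), and a roster generator reproducing the published
participant-flow margins. It does not attempt the full covariate joint
distribution of a real trial population, unmeasured confounding,
measurement error in self-reported drinking, outcome state dependence,
or non-monotone intermittent missingness (an optional wave-skip mask
emulates staggered questionnaire administration but is off by default).
Passing tests therefore demonstrate internal validity of the machinery
under correct specification, not robustness to the misspecifications
real data would add.

## Numerical and design details

* Exposure models: `nnet::multinom` (probabilities sum to 1 by
  construction); a one-vs-rest mode fits four binary logistic models
  and renormalises, recording the pre-normalisation sums as an
  agreement diagnostic. Constant predictors are dropped with a message;
  non-convergence is an error naming the predictors.
* Treatment probabilities at or below the machine floor raise an error
  listing the offending rows (positivity violations should fail loudly).
* Robust variance: `sandwich::vcovCL` (HC0) clustered on participant;
  CIs are `exp(log OR ± 1.96 SE)`; a joint 3-df Wald test across the
  category terms accompanies the per-contrast p-values, mirroring the
  one-p-per-block convention of published tables.
* The unadjusted comparator uses the same estimating machinery with
  unit weights, so unadjusted vs weighted differences are attributable
  to the weights alone.
* E-values use the risk-ratio-scale formula
  $E = R + \sqrt{R(R-1)}$ with $R$ the OR (reciprocal first if below
  1; `rare_outcome = FALSE` applies the common-outcome $\sqrt{R}$
  conversion first). The ~9%-per-wave outcome is treated as rare by
  default — the choice that reproduces published E-value tables.
  Report rounding is R's default half-even at 2 decimals; full
  precision is kept internally.
* Partially completed CES-D-10 questionnaires are not imputed: a
  missing total at an observed wave is treated as a censored outcome
  wave and handled by IPCW.
* Abstention requires zero consumption; records with drinking days but
  no drinks (or vice versa, or heavy episodic drinking with zero
  consumption) are rejected as inconsistent rather than guessed.
* Sensitivity scenarios re-estimate their weights on their own subsets:
  each subset defines its own pseudo-population.
* The power calculator is a generic simulation tool (inject a
  multiplicative female-OR shift, run the weighted interaction
  analysis, count rejections of the joint Wald test); it encodes no
  claims about any particular published power statement.

## Problem sizes used by the test suite

The package's own checks run the full default cohort (16,563
participants, six waves) once for the structural and
bias-demonstration checks, a 10,000-participant cohort for the balance
criterion, and 200 replicates of 2,000 participants over four waves for
parameter recovery and CI coverage (observed: per-category mean log-OR
bias below 0.03, coverage 95–96%). These sizes give Monte-Carlo
standard errors comfortably below the tolerances being asserted while
keeping a full test run in a few minutes.

## Known limitations

* The estimand of the per-protocol analysis is the static always-one-
  category regime; with strong exposure→confounder feedback the
  single-term marginal model would be a genuine approximation (see
  above), and the package does not fit history-saturated MSMs.
* Only logistic-family propensity and censoring models are provided —
  no machine-learning weight estimators.
* No doubly robust or TMLE estimator; no continuous dose–response.
* E-values are provided for odds ratios only.
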