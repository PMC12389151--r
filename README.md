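# jshape

Marginal structural models for a four-level time-varying drinking
exposure and a repeated binary depression outcome in longitudinal
cohorts of older adults.

Observational cohorts repeatedly show a J-shaped association between
alcohol consumption and depression — risk lowest among moderate
drinkers, elevated among abstainers and above-guideline drinkers — but
the pattern is exactly what time-varying confounding, sick-quitter
misclassification and informative dropout would also produce. `jshape`
is a tested pipeline for analysing that question causally: it
classifies exposure (abstainer / occasional / moderate /
above-guideline, with sex-specific weekly limits and heavy-episodic
overrides), scores the CES-D-10 depression screen (items 0–3,
positive-mood items reverse-coded, probable depression at a total ≥ 8,
or ≥ 10 in sensitivity analyses), and estimates the marginal structural
model

logit P(Y<sub>t+1</sub><sup>ā</sup> = 1) = β₀ + β<sub>A</sub>[a<sub>t</sub>]

by inverse-probability weighting: a multinomial
treatment model gives IPTW, pooled logistic retention models give
IPCW, the product is (optionally) trimmed at the 2nd–98th percentiles,
covariate balance is checked with standardized mean differences
(|SMD| < 0.10), and the weighted outcome model is fitted as logistic
estimating equations with independence working correlation and a
participant-clustered sandwich variance. Intention-to-treat (baseline
category carried forward) and per-protocol (annually time-updated
category, the primary analysis) contrasts are reported with robust 95%
CIs, a sensitivity suite (excluding former drinkers, excluding the
baseline-depressed, cutoff 10), sex-interaction analyses, and E-values
(E = R + √(R(R−1))) quantifying robustness to unmeasured confounding.

Because the motivating cohort data are access-controlled, the package
ships a first-class synthetic-cohort generator with the same structure
— time-varying confounding with treatment feedback, 55–90% per-wave
exposure persistence, informative monotone dropout, a known J-shaped
causal effect — plus a counterfactual Monte-Carlo oracle
(`true_marginal_effects()`) that computes the true marginal odds
ratios each analysis should recover.

## Worked example

```r
library(jshape)

cfg    <- sim_config(n_participants = 5000, n_waves = 4, seed = 42)
cohort <- simulate_cohort(cfg)
cohort
#> <cohort_table> 5000 participants x 4 waves (18005 observed rows)
#>   baseline covariates:    sex, age, education, smoker
#>   time-updated covariates:health_burden
#>   baseline exposure: abstainer 26.5%, occasional 21.0%, moderate 32.5%, above_guideline 19.9%

pp <- run_pp(cohort)          # per-protocol MSM: weights, balance, fit
pp$weighted_fit
#> <msm_fit> PP: 13005 observations, 4657 participants
#>   contrast                           OR  [   lo,    hi]  p
#>   abstainer vs moderate           1.125  [0.923, 1.373]  0.24
#>   occasional vs moderate          1.073  [0.857, 1.344]  0.54
#>   above_guideline vs moderate     1.094  [0.878, 1.363]  0.43
#>   joint Wald (3 df) p = 0.709

true_marginal_effects(cfg, n_mc = 50000)
#> <truth_record> counterfactual Monte Carlo, n_mc = 50000
#>         category       risk odds_ratio mc_se_log_or
#>        abstainer 0.09762814     1.1895       0.0000
#>       occasional 0.09223224     1.1171       0.0000
#>         moderate 0.08337087     1.0000       0.0000
#>  above_guideline 0.09615721     1.1697       0.0000

add_evalues(pp$weighted_fit$estimates)[, c("odds_ratio", "evalue", "evalue_ci")]
#>   odds_ratio evalue evalue_ci
#> 1      1.125  1.501         1
#> 2      1.073  1.354         1
#> 3      1.094  1.414         1
```

The weighted odds ratios track the oracle's true marginal values
(1.19 / 1.12 / 1.17) within sampling error at this modest cohort size —
the J-shape is there but, as the CIs show, n = 5,000 over four waves is
underpowered for effects of this size; at the default 16,563
participants and six waves the weighted CIs exclude 1 while an
unadjusted fit is several robust standard errors off the truth. Each
E-value is the minimum odds-ratio-scale association an unmeasured
confounder would need with both exposure and outcome to explain the
estimate away; `evalue_ci` is 1 here because each CI already contains
the null.

The full pipeline — exclusions, PP + ITT, three sensitivity scenarios,
interactions, E-values, CSV/markdown report — runs from one config:

```r
report <- run_analysis(analysis_config(
  simulation = sim_config(seed = 1), seed = 1, output_dir = "report"))
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/jshape` (`jshape simulate|analyze|evalue|power ...`).

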