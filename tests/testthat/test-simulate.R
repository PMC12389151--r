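test_that("simulation is deterministic given the seed and leaves the RNG alone", {
  cfg <- sim_config(n_participants = 200, n_waves = 3, seed = 77)
  set.seed(1); before <- runif(1)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  set.seed(1); expect_identical(runif(1), before)
  # a different seed gives a different cohort
  c <- simulate_cohort(sim_config(n_participants = 200, n_waves = 3, seed = 78))
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("generated cohorts satisfy the data model invariants", {
  cohort <- simulate_cohort(sim_config(n_participants = 400, n_waves = 5,
                                       seed = 21))
  expect_no_error(validate_cohort(cohort, strict = TRUE))
  obs <- cohort[!cohort$censored, ]
  # raw drinking fields re-classify to the stored category
  recls <- classify_alcohol(obs$days_per_week, obs$drinks_per_day,
                            obs$heavy_episodic, obs$sex)
  expect_equal(as.character(recls), as.character(obs$alcohol_category))
  # retention is monotone nonincreasing across waves
  ret <- tapply(!cohort$censored, cohort$wave, sum)
  expect_true(all(diff(ret) <= 0))
  # former drinkers are a subset of baseline abstainers
  base <- cohort[cohort$wave == 0, ]
  expect_true(all(base$alcohol_category[base$former_drinker] == "abstainer"))
})

test_that("config validation rejects degenerate settings", {
  expect_error(sim_config(baseline_category_probs = c(0.5, 0.5, 0, 0)),
               "empty exposure category")
  expect_error(sim_config(baseline_category_probs = c(0.4, 0.3, 0.2, 0.2)),
               "summing to 1")
  expect_error(sim_config(n_waves = 1), "n_waves")
  expect_error(sim_config(persistence = c(1, 0.5, 0.5, 0.5)), "persistence")
  expect_error(sim_config(conditional_log_or = log(c(1.2, 1.1, 1.3, 1.2))),
               "reference")
  expect_error(sim_config(censoring_base_rate = 0.7), "censoring_base_rate")
})

test_that("the counterfactual oracle recovers the null exactly", {
  cfg <- sim_config(n_participants = 500, n_waves = 4, seed = 2,
                    conditional_log_or = c(0, 0, 0, 0))
  truth <- true_marginal_effects(cfg, n_mc = 5000)
  expect_close(truth$odds_ratio, rep(1, 4), tol = 0.02)
  expect_true(all(truth$mc_se[-3] > 0))
})

test_that("marginal odds ratios are attenuated relative to conditional ones", {
  # conditional OR 2 for abstainers with a strong confounder effect on the
  # outcome: the marginal OR is strictly between 1 and 2 (noncollapsibility)
  cfg <- sim_config(n_participants = 500, n_waves = 4, seed = 2,
                    conditional_log_or = c(log(2), 0, 0, 0),
                    confounder_effects = list(on_exposure = c(0.6, 0.3, 0, 0.4),
                                              on_outcome = 2,
                                              on_censoring = 0.3))
  truth <- true_marginal_effects(cfg, n_mc = 20000)
  or_abst <- truth$odds_ratio[1]
  expect_gt(or_abst, 1)
  expect_lt(or_abst, 2)
  # and visibly below the conditional value, not a rounding artifact
  expect_lt(or_abst, 1.95)
})

test_that("oracle Monte-Carlo error shrinks roughly with sqrt(n_mc)", {
  cfg <- sim_config(n_participants = 500, n_waves = 4, seed = 2)
  se1 <- true_marginal_effects(cfg, n_mc = 2000, seed = 5)$mc_se[1]
  se2 <- true_marginal_effects(cfg, n_mc = 8000, seed = 5)$mc_se[1]
  expect_lt(se2, se1)
  expect_close(se1 / se2, 2, tol = 0.6)
})

test_that("with no confounding and no censoring, naive and weighted agree", {
  cfg <- sim_config(n_participants = 3000, n_waves = 3, seed = 13,
                    confounder_effects = list(on_exposure = c(0, 0, 0, 0),
                                              on_outcome = 0.4,
                                              on_censoring = 0),
                    female_by_category = rep(0.539, 4),
                    censoring_base_rate = 0,
                    l_exposure_effect = c(0, 0, 0, 0))
  cohort <- simulate_cohort(cfg)
  expect_true(all(!cohort$censored))
  pp <- suppressMessages(run_pp(cohort, balance = FALSE))
  w <- pp$weighted_fit$estimates$log_or
  u <- pp$unadjusted_fit$estimates$log_or
  # weights are near-constant, so the two fits nearly coincide
  expect_close(w, u, tol = 0.06)
})
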