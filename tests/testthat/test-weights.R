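test_that("intercept-only exposure model returns empirical frequencies", {
  cohort <- manual_cohort(matrix(rep(c(1L, 2L, 3L, 3L, 4L), each = 1),
                                 ncol = 1))
  # age varies in the helper; make every covariate constant to force the
  # intercept-only limit
  df <- as.data.frame(cohort)
  df$age <- 75; df$sex <- "female"; df$health_burden <- 0
  cohort <- cohort_table(df, baseline_covariates = c("sex", "age"),
                         time_updated_covariates = "health_burden")
  expect_message(ef <- fit_exposure_model(cohort), "constant predictor")
  freq <- prop.table(table(df$alcohol_category))
  for (k in seq_along(alcohol_levels)) {
    expect_close(ef$probabilities[, k], rep(freq[k], 5), tol = 1e-4)
  }
})

test_that("multinomial probabilities sum to one on every row", {
  cohort <- simulate_cohort(sim_config(n_participants = 400, n_waves = 4,
                                       seed = 31))
  ef <- fit_exposure_model(cohort)
  expect_true(all(abs(rowSums(ef$probabilities) - 1) < 1e-10))
  expect_true(all(ef$p_observed > 0 & ef$p_observed < 1))
})

test_that("one-vs-rest probabilities renormalise and log their raw sums", {
  cohort <- simulate_cohort(sim_config(n_participants = 400, n_waves = 3,
                                       seed = 31))
  ef <- fit_exposure_model(cohort, method = "one_vs_rest")
  expect_true(all(abs(rowSums(ef$probabilities) - 1) < 1e-10))
  expect_true(all(is.finite(ef$prenorm_sums)))
  expect_close(mean(ef$prenorm_sums), 1, tol = 0.1)
})

test_that("exposure-model coefficients recover the generator at n = 10,000", {
  cfg <- sim_config(n_participants = 10000, n_waves = 2, seed = 8)
  cohort <- simulate_cohort(cfg)
  base <- cohort[cohort$wave == 0, ]
  attr(base, "n_waves") <- 1L
  ef <- fit_exposure_model(base, covariates = c("health_burden", "sex"))
  sm <- summary(ef$models$baseline)
  co <- stats::coef(ef$models$baseline)
  se <- sm$standard.errors
  # truth from the generating mixture: L slope mu_a - mu_ref per category,
  # sex slope logit(q_a) - logit(q_ref) (moderate is absorbed in multinom's
  # first-level reference = abstainer, so compare pairwise differences)
  p <- cfg$baseline_category_probs
  lam <- cfg$confounder_effects$on_exposure
  q <- cfg$female_by_category
  lamF <- qlogis(q) - qlogis(q[1])
  lamL <- lam - lam[1]
  for (row in rownames(co)) {
    k <- match(row, alcohol_levels)
    expect_lt(abs(co[row, "health_burden"] - lamL[k]), 2 * se[row, "health_burden"] + 1e-9)
    expect_lt(abs(co[row, "sexmale"] - (-lamF[k])), 2 * se[row, "sexmale"] + 1e-9)
  }
})

test_that("IPTW is the reciprocal probability with the documented identities", {
  probs <- matrix(c(0.25, 0.25, 0.25, 0.25,
                    0.1, 0.2, 0.3, 0.4), nrow = 2, byrow = TRUE,
                  dimnames = list(NULL, alcohol_levels))
  obs <- factor(c("abstainer", "above_guideline"), levels = alcohol_levels)
  w <- compute_iptw(probs, obs, cumulative = FALSE)
  expect_equal(w$iptw, c(4, 2.5))
  # cumulative product within participant
  wc <- compute_iptw(rbind(probs, probs), factor(rep(obs, 2), levels = alcohol_levels),
                     cumulative = TRUE,
                     participant_id = c("a", "b", "a", "b"),
                     wave = c(0L, 0L, 1L, 1L))
  expect_equal(wc$iptw[wc$participant_id == "a"], c(4, 16))
  # degenerate probabilities error with row references
  probs0 <- probs; probs0[1, 1] <- 1e-300
  expect_error(compute_iptw(probs0, obs, cumulative = FALSE), "machine floor")
})

test_that("weight means match the textbook identities on simulated data", {
  cohort <- simulate_cohort(sim_config(n_participants = 6000, n_waves = 2,
                                       seed = 12))
  ef <- fit_exposure_model(cohort)
  unstab <- compute_iptw(ef, stabilized = FALSE, cumulative = FALSE)
  stab <- compute_iptw(ef, stabilized = TRUE, cumulative = FALSE)
  # E[1 / P(A | X)] summed over categories equals the category count
  expect_close(mean(unstab$iptw), 4, tol = 0.25)
  # stabilised weights have mean 1
  expect_close(mean(stab$iptw), 1, tol = 0.05)
  # history-conditional numerator also gives mean ~1 per wave
  stab_h <- compute_iptw(ef, stabilized = TRUE, cumulative = FALSE,
                         numerator = "history")
  expect_close(mean(stab_h$iptw), 1, tol = 0.05)
})

test_that("censoring weights cumulate reciprocals and stay >= 1", {
  ret <- data.frame(participant_id = c("a", "a"), wave = c(1L, 2L),
                    p_retain = c(0.8, 0.8))
  expect_equal(compute_ipcw(ret)$ipcw, c(1.25, 1.5625))
  expect_equal(compute_ipcw(ret, cumulative = FALSE)$ipcw, c(1.25, 1.25))
  expect_error(compute_ipcw(data.frame(participant_id = "a", wave = 1L,
                                       p_retain = 1.2)), "\\(0, 1\\]")
  # no censoring anywhere: all retention probabilities 1, IPCW exactly 1
  cohort <- simulate_cohort(sim_config(n_participants = 300, n_waves = 3,
                                       seed = 4, censoring_base_rate = 0))
  expect_message(cf <- fit_censoring_model(cohort), "retention set to 1")
  expect_true(all(cf$p_retain == 1))
  expect_true(all(compute_ipcw(cf)$ipcw == 1))
})

test_that("censoring weights move weighted prevalence toward the full-data value", {
  # simulate with informative censoring, and compare against the same
  # generating process with censoring switched off (the oracle full data)
  cfg <- sim_config(n_participants = 8000, n_waves = 4, seed = 14,
                    censoring_base_rate = 0.12,
                    confounder_effects = list(on_exposure = c(0.6, 0.3, 0, 0.4),
                                              on_outcome = 0.8,
                                              on_censoring = 1.0))
  full <- simulate_cohort({cf0 <- cfg; cf0$censoring_base_rate <- 0; cf0})
  cens <- simulate_cohort(cfg)
  target <- mean(full$depressed[full$wave == 3], na.rm = TRUE)
  obs3 <- cens[cens$wave == 3 & !cens$censored, ]
  naive <- mean(obs3$depressed)
  cf <- fit_censoring_model(cens)
  ipcw <- compute_ipcw(cf)
  w3 <- ipcw$ipcw[match(paste(obs3$participant_id, 3),
                        paste(ipcw$participant_id, ipcw$wave))]
  weighted <- sum(w3 * obs3$depressed) / sum(w3)
  expect_lt(abs(weighted - target), abs(naive - target))
})

test_that("trimming follows the nearest-rank percentile rule", {
  # uniform weights: degenerate distribution, nothing excluded
  ws <- combine_and_trim(rep(2, 100), rep(1, 100))
  expect_equal(attr(ws, "n_excluded"), 0L)
  # 1000 distinct weights at 2/98: exactly 20 per tail
  set.seed(6)
  w <- sample(seq(0.1, 50, length.out = 1000))
  ws <- combine_and_trim(w, rep(1, 1000))
  expect_equal(attr(ws, "n_excluded"), 40L)
  expect_equal(sum(ws$trimmed), 40L)
  srt <- sort(w)
  expect_true(all(srt[1:20] %in% ws$combined[ws$trimmed]))
  expect_true(all(srt[981:1000] %in% ws$combined[ws$trimmed]))
  # capping preserves the row count and bounds the weights
  wc <- combine_and_trim(w, rep(1, 1000), mode = "cap")
  expect_equal(sum(is.na(wc$weight)), 0L)
  expect_equal(sum(wc$trimmed), 0L)
  cuts <- attr(wc, "cuts")
  expect_true(all(wc$weight >= cuts[1] & wc$weight <= cuts[2]))
  # trimming at (0, 100) is the identity
  wi <- combine_and_trim(w, rep(1, 1000), lower_pct = 0, upper_pct = 100)
  expect_equal(wi$weight, w)
  expect_equal(attr(wi, "n_excluded"), 0L)
})

test_that("standardized mean differences match hand computation", {
  expect_equal(standardized_mean_difference(c(1, 2, 3, 1, 2, 3),
                                            c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)),
               0)
  # group means 0 and 1, both SD 1 (population variance): SMD = 1
  set.seed(2)
  g1 <- rnorm(20000, 1, 1); g2 <- rnorm(20000, 0, 1)
  smd <- standardized_mean_difference(c(g1, g2),
                                      rep(c(TRUE, FALSE), each = 20000))
  expect_close(smd, 1, tol = 0.03)
  # binary covariate uses the proportion variance: p1=0.8, p2=0.2
  v <- rep(c(1, 0, 1, 0), times = c(8, 2, 2, 8))
  g <- rep(c(TRUE, FALSE), each = 10)
  expect_equal(standardized_mean_difference(v, g),
               (0.8 - 0.2) / sqrt((0.16 + 0.16) / 2))
  # weights that equalise the means drive |SMD| under 0.10
  v2 <- c(rep(1, 30), rep(0, 10), rep(1, 10), rep(0, 30))
  g2m <- rep(c(TRUE, FALSE), each = 40)
  w <- ifelse(g2m == (v2 == 1), 1, 3)
  expect_lt(abs(standardized_mean_difference(v2, g2m, w)), 0.10)
  # zero pooled variance: equal means fine, unequal means an error
  expect_equal(standardized_mean_difference(c(1, 1, 1, 1), c(TRUE, TRUE, FALSE, FALSE)), 0)
  expect_error(standardized_mean_difference(c(5, 5, 2, 2), c(TRUE, TRUE, FALSE, FALSE)),
               "zero pooled variance")
  expect_error(standardized_mean_difference(1:3, c(TRUE, TRUE, TRUE)),
               "non-empty")
})

test_that("the balance report is antisymmetric and finite", {
  cohort <- simulate_cohort(sim_config(n_participants = 1500, n_waves = 3,
                                       seed = 17))
  an <- lag_exposure(cohort)
  rep1 <- balance_report(an, covariates = c("health_burden", "sex", "age"))
  expect_true(all(is.finite(rep1$smd_unweighted)))
  expect_identical(rep1$flag_unweighted, abs(rep1$smd_unweighted) >= 0.10)
  # swapping the contrast direction flips the sign
  rep_m <- balance_report(an, covariates = "health_burden",
                          reference = "abstainer")
  a_vs_m <- rep1$smd_unweighted[rep1$covariate == "health_burden" &
                                  rep1$contrast == "abstainer vs moderate"]
  m_vs_a <- rep_m$smd_unweighted[rep_m$covariate == "health_burden" &
                                   rep_m$contrast == "moderate vs abstainer"]
  expect_equal(a_vs_m, -m_vs_a)
  # markdown rendering covers every row
  md <- format_balance_markdown(rep1)
  expect_length(md, nrow(rep1) + 2L)
})
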