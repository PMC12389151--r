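#' Estimate inverse-probability weights for an analysis table
#'
#' Composes the weight engine for a lagged analysis table: fits the
#' exposure model (time-updated for per-protocol, baseline-only for
#' intention-to-treat), computes IPTW at the exposure wave, fits the
#' censoring model, computes cumulative IPCW at the outcome wave, and
#' combines and trims the product. Percentiles for trimming are computed
#' on the rows that enter the outcome model (observed outcome).
#'
#' @param cohort A [cohort_table()].
#' @param analysis Output of [lag_exposure()] on the same cohort.
#' @param exposure `"time_updated"` (per-protocol weighting) or
#'   `"baseline"` (point-treatment weighting of the baseline category).
#' @param stabilized,cumulative,numerator Passed to [compute_iptw()];
#'   stabilised history-numerator cumulative weights are the default, the
#'   well-behaved choice for a persistent exposure.
#' @param censoring_covariates Passed to [fit_censoring_model()].
#' @param trim Length-2 percentile band for [combine_and_trim()].
#' @param trim_mode `"exclude"` or `"cap"`.
#' @param covariates,exposure_method Passed to [fit_exposure_model()].
#' @return List with `weight_set` (aligned to the model rows), `fit_rows`
#'   (logical index into `analysis` of rows with observed outcome),
#'   `iptw`, `ipcw` (aligned to all `analysis` rows), and the component
#'   fits.
#' @export
estimate_weights <- function(cohort, analysis,
                             exposure = c("time_updated", "baseline"),
                             stabilized = TRUE, cumulative = TRUE,
                             numerator = "history",
                             censoring_covariates = "time_updated",
                             trim = c(2, 98), trim_mode = "exclude",
                             covariates = NULL,
                             exposure_method = "multinomial") {
  exposure <- match.arg(exposure)
  if (exposure == "time_updated") {
    ef <- fit_exposure_model(cohort, covariates = covariates,
                             method = exposure_method)
    iptw_df <- compute_iptw(ef, stabilized = stabilized,
                            cumulative = cumulative, numerator = numerator)
    idx <- match(paste(analysis$participant_id, analysis$exposure_wave),
                 paste(iptw_df$participant_id, iptw_df$wave))
  } else {
    base <- cohort[cohort$wave == 0L, , drop = FALSE]
    attr(base, "n_waves") <- 1L
    ef <- fit_exposure_model(base, covariates = covariates,
                             method = exposure_method)
    iptw_df <- compute_iptw(ef, stabilized = stabilized, cumulative = FALSE)
    idx <- match(analysis$participant_id, iptw_df$participant_id)
  }
  iptw <- iptw_df$iptw[idx]

  cf <- fit_censoring_model(cohort, covariates = censoring_covariates)
  ipcw_df <- compute_ipcw(cf, cumulative = TRUE)
  cidx <- match(paste(analysis$participant_id, analysis$outcome_wave),
                paste(ipcw_df$participant_id, ipcw_df$wave))
  ipcw <- ipcw_df$ipcw[cidx]
  ipcw[is.na(ipcw)] <- 1   # outcome wave beyond risk table (no censoring)

  fit_rows <- !analysis$outcome_censored
  ws <- combine_and_trim(iptw[fit_rows], ipcw[fit_rows],
                         lower_pct = trim[1L], upper_pct = trim[2L],
                         mode = trim_mode)
  list(weight_set = ws, fit_rows = fit_rows, iptw = iptw, ipcw = ipcw,
       exposure_fit = ef, censoring_fit = cf)
}

#' Weighted repeated-measures logistic outcome model
#'
#' Fits logit-link binomial estimating equations for the repeated binary
#' outcome with observation weights and an independence working
#' correlation, clustering on participant for the robust (sandwich)
#' variance -- the standard estimator for marginal structural models with
#' inverse-probability weights. With unit weights and a single wave this
#' reduces exactly to ordinary logistic regression. Only the independence
#' working correlation is offered: combined with inverse-probability
#' weights, non-independence working correlations can yield inconsistent
#' estimates.
#'
#' @param analysis Analysis table from [lag_exposure()]; rows with
#'   `outcome_censored` are excluded (they contribute through the
#'   censoring weights of the retained rows).
#' @param weights Observation weights aligned with `analysis` rows (`NA`
#'   for trimmed rows, which are excluded); `NULL` for unit weights.
#' @param reference Reference exposure category.
#' @param analysis_tag Label stored with the estimates.
#' @param exposure_col Column holding the exposure factor.
#' @return An `msm_fit`: list with `estimates` (one row per non-reference
#'   category: odds ratio, robust 95% CI, robust SE of the log-OR, Wald
#'   p), `joint_p` (3-df Wald test across categories), the underlying
#'   `fit`, robust `vcov`, and bookkeeping counts.
#' @export
fit_weighted_outcome_model <- function(analysis, weights = NULL,
                                       reference = "moderate",
                                       analysis_tag = "PP",
                                       exposure_col = "alcohol_category") {
  rows <- !analysis$outcome_censored
  if (!is.null(weights)) rows <- rows & !is.na(weights)
  dat <- analysis[rows, , drop = FALSE]
  w <- if (is.null(weights)) rep(1, nrow(dat)) else weights[rows]
  dat$.y <- as.numeric(dat$outcome)
  dat$.a <- stats::relevel(factor(dat[[exposure_col]], levels = alcohol_levels),
                           ref = reference)
  dat$.w <- w
  fit <- stats::glm(.y ~ .a, data = dat, weights = .w,
                    family = stats::quasibinomial())
  if (!fit$converged) {
    stop("outcome model did not converge; max weight ", max(w),
         ", check for separation across exposure categories")
  }
  V <- sandwich::vcovCL(fit, cluster = dat$participant_id, type = "HC0")
  cf <- stats::coef(fit)
  levs <- setdiff(levels(dat$.a), reference)
  terms <- paste0(".a", levs)
  est <- data.frame(
    contrast = paste(levs, "vs", reference),
    log_or = cf[terms],
    se_log_or = sqrt(diag(V)[terms]),
    row.names = NULL)
  est$odds_ratio <- exp(est$log_or)
  est$ci_low <- exp(est$log_or - 1.96 * est$se_log_or)
  est$ci_high <- exp(est$log_or + 1.96 * est$se_log_or)
  est$p_value <- 2 * stats::pnorm(-abs(est$log_or / est$se_log_or))
  est$analysis <- analysis_tag
  est$n_obs <- nrow(dat)
  est$n_participants <- length(unique(dat$participant_id))
  b <- cf[terms]
  Vb <- V[terms, terms]
  stat <- drop(t(b) %*% solve(Vb, b))
  structure(list(estimates = est,
                 joint_p = stats::pchisq(stat, df = length(b), lower.tail = FALSE),
                 fit = fit, vcov = V, reference = reference,
                 weight_summary = summary(w),
                 n_obs = nrow(dat),
                 n_participants = est$n_participants[1L]),
            class = "msm_fit")
}

#' @export
print.msm_fit <- function(x, ...) {
  cat(sprintf("<msm_fit> %s: %d observations, %d participants\n",
              x$estimates$analysis[1L], x$n_obs, x$n_participants))
  df <- x$estimates
  cat(sprintf("  %-30s %6s  [%5s, %5s]  p\n", "contrast", "OR", "lo", "hi"))
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-30s %6.3f  [%5.3f, %5.3f]  %.2g\n",
                df$contrast[i], df$odds_ratio[i], df$ci_low[i], df$ci_high[i],
                df$p_value[i]))
  }
  cat(sprintf("  joint Wald (%d df) p = %.3g\n", nrow(df), x$joint_p))
  invisible(x)
}

#' Exposure-by-modifier interaction on the weighted pseudo-population
#'
#' Adds modifier-by-category product terms to the weighted outcome model
#' and reports the per-category interaction odds ratios (robust CIs) plus
#' a joint Wald test over all interaction terms. The reference category
#' and the modifier's reference level carry no interaction term.
#'
#' @inheritParams fit_weighted_outcome_model
#' @param modifier Column name of a binary or categorical covariate.
#' @return An `msm_fit`-like list whose `estimates` rows are the
#'   interaction contrasts; `joint_p` tests all interaction terms at once.
#' @export
fit_interaction <- function(analysis, weights = NULL, modifier,
                            reference = "moderate",
                            analysis_tag = paste0("interaction:", modifier)) {
  stopifnot(modifier %in% names(analysis))
  rows <- !analysis$outcome_censored
  if (!is.null(weights)) rows <- rows & !is.na(weights)
  dat <- analysis[rows, , drop = FALSE]
  m <- dat[[modifier]]
  if (length(unique(m[!is.na(m)])) < 2L) {
    stop("modifier '", modifier, "' is constant")
  }
  dat$.m <- if (is.numeric(m)) m else factor(m)
  dat$.y <- as.numeric(dat$outcome)
  dat$.a <- stats::relevel(factor(dat$alcohol_category, levels = alcohol_levels),
                           ref = reference)
  dat$.w <- if (is.null(weights)) rep(1, nrow(dat)) else weights[rows]
  fit <- stats::glm(.y ~ .a * .m, data = dat, weights = .w,
                    family = stats::quasibinomial())
  V <- sandwich::vcovCL(fit, cluster = dat$participant_id, type = "HC0")
  cf <- stats::coef(fit)
  int_terms <- grep("^\\.a.*:\\.m", names(cf), value = TRUE)
  est <- data.frame(
    contrast = sub("^\\.a(.*):\\.m(.*)$", "\\1 x \\2", int_terms),
    log_or = cf[int_terms],
    se_log_or = sqrt(diag(V)[int_terms]),
    row.names = NULL)
  est$odds_ratio <- exp(est$log_or)
  est$ci_low <- exp(est$log_or - 1.96 * est$se_log_or)
  est$ci_high <- exp(est$log_or + 1.96 * est$se_log_or)
  est$p_value <- 2 * stats::pnorm(-abs(est$log_or / est$se_log_or))
  est$analysis <- analysis_tag
  est$n_obs <- nrow(dat)
  est$n_participants <- length(unique(dat$participant_id))
  b <- cf[int_terms]
  Vb <- V[int_terms, int_terms, drop = FALSE]
  stat <- drop(t(b) %*% solve(Vb, b))
  structure(list(estimates = est,
                 joint_p = stats::pchisq(stat, df = length(b), lower.tail = FALSE),
                 fit = fit, vcov = V, reference = reference,
                 n_obs = nrow(dat), n_participants = est$n_participants[1L]),
            class = "msm_fit")
}

#' Per-protocol analysis: time-updated exposure, full weighting pipeline
#'
#' The primary analysis. Re-derives the binary outcome at the requested
#' CES-D-10 cutoff, builds the lagged analysis table, estimates
#' time-updated treatment weights and cumulative censoring weights, trims,
#' and fits the weighted outcome model; an unadjusted (unit-weight,
#' cluster-robust) fit of the same rows is reported alongside.
#'
#' @param cohort A [cohort_table()] that has passed exclusions.
#' @param cutoff CES-D-10 cutoff for the outcome (8 or 10).
#' @param lag_waves Exposure--outcome lag in waves.
#' @param balance Also compute the covariate [balance_report()]?
#' @inheritParams estimate_weights
#' @return An `msm_analysis`: list with `estimates` (weighted + unadjusted
#'   rows), the two `msm_fit`s, the `weight_set`, `balance`, and component
#'   fits.
#' @export
run_pp <- function(cohort, cutoff = 8L, lag_waves = 1L,
                   stabilized = TRUE, cumulative = TRUE,
                   censoring_covariates = "time_updated",
                   trim = c(0, 100), trim_mode = "exclude",
                   covariates = NULL, exposure_method = "multinomial",
                   balance = TRUE) {
  run_msm(cohort, exposure = "time_updated", tag = "PP", cutoff = cutoff,
          lag_waves = lag_waves, stabilized = stabilized,
          cumulative = cumulative, censoring_covariates = censoring_covariates,
          trim = trim, trim_mode = trim_mode, covariates = covariates,
          exposure_method = exposure_method, balance = balance)
}

#' Intention-to-treat analysis: baseline exposure carried forward
#'
#' Classifies every participant by the baseline category regardless of
#' later changes, weights by the baseline (point-treatment) propensity and
#' cumulative censoring weights, and fits the same weighted outcome model
#' as [run_pp()]. With no category switching, ITT and PP coincide.
#'
#' @inheritParams run_pp
#' @return An `msm_analysis` (see [run_pp()]).
#' @export
run_itt <- function(cohort, cutoff = 8L, lag_waves = 1L,
                    stabilized = TRUE,
                    censoring_covariates = "time_updated",
                    trim = c(0, 100), trim_mode = "exclude",
                    covariates = NULL, exposure_method = "multinomial",
                    balance = TRUE) {
  run_msm(cohort, exposure = "baseline", tag = "ITT", cutoff = cutoff,
          lag_waves = lag_waves, stabilized = stabilized, cumulative = FALSE,
          censoring_covariates = censoring_covariates, trim = trim,
          trim_mode = trim_mode, covariates = covariates,
          exposure_method = exposure_method, balance = balance)
}

run_msm <- function(cohort, exposure, tag, cutoff, lag_waves, stabilized,
                    cumulative, censoring_covariates, trim, trim_mode,
                    covariates, exposure_method, balance) {
  step <- "outcome dichotomisation"
  out <- tryCatch({
    cohort$depressed <- classify_depression(cohort$cesd_score, cutoff)
    step <- "lagged analysis table"
    analysis <- lag_exposure(cohort, lag_waves = lag_waves)
    if (exposure == "baseline") {
      base <- cohort[cohort$wave == 0L, , drop = FALSE]
      analysis$alcohol_category <-
        base$alcohol_category[match(analysis$participant_id,
                                    base$participant_id)]
    }
    step <- "weight estimation"
    wts <- estimate_weights(cohort, analysis, exposure = exposure,
                            stabilized = stabilized, cumulative = cumulative,
                            censoring_covariates = censoring_covariates,
                            trim = trim, trim_mode = trim_mode,
                            covariates = covariates,
                            exposure_method = exposure_method)
    w_full <- rep(NA_real_, nrow(analysis))
    w_full[wts$fit_rows] <- wts$weight_set$weight
    step <- "weighted outcome model"
    wfit <- fit_weighted_outcome_model(analysis, weights = w_full,
                                       analysis_tag = tag)
    ufit <- fit_weighted_outcome_model(analysis, weights = NULL,
                                       analysis_tag = paste0(tag, "_unadjusted"))
    step <- "balance diagnostics"
    bal <- NULL
    if (balance) {
      covs <- covariates %||%
        unique(unlist(covariate_roles(cohort), use.names = FALSE))
      bal <- balance_report(analysis, weights = w_full, covariates = covs,
                            strata = "exposure_wave")
    }
    structure(list(estimates = rbind(wfit$estimates, ufit$estimates),
                   weighted_fit = wfit, unadjusted_fit = ufit,
                   weight_set = wts$weight_set, weights = w_full,
                   balance = bal, analysis = analysis,
                   exposure_fit = wts$exposure_fit,
                   censoring_fit = wts$censoring_fit,
                   cutoff = cutoff, tag = tag),
              class = "msm_analysis")
  }, error = function(e) {
    stop("[", tag, " / ", step, "] ", conditionMessage(e), call. = FALSE)
  })
  out
}

#' @export
print.msm_analysis <- function(x, ...) {
  cat(sprintf("<msm_analysis> %s (CES-D-10 cutoff %d)\n", x$tag, x$cutoff))
  print(x$weighted_fit)
  cat("unadjusted:\n")
  print(x$unadjusted_fit)
  invisible(x)
}
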