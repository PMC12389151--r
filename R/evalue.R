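#' E-value for a point estimate
#'
#' The E-value is the minimum strength of association, on the risk-ratio
#' scale, that an unmeasured confounder would need with both exposure and
#' outcome, conditional on measured covariates, to fully explain away an
#' observed association. For an estimate `R >= 1`,
#' `E = R + sqrt(R * (R - 1))`; estimates below 1 are first inverted
#' (`E(x) = E(1/x)` exactly). With a rare outcome (the default; per-wave
#' prevalence near 9% is treated as rare) the odds ratio approximates the
#' risk ratio and enters the formula directly; `rare_outcome = FALSE`
#' applies the common-outcome square-root conversion `R <- sqrt(R)` first.
#'
#' @param or_value Odds ratio(s), strictly positive.
#' @param rare_outcome Treat the OR as a risk ratio (default) or apply the
#'   square-root conversion first.
#' @return E-value(s), always `>= 1`, equal to 1 exactly when the OR is 1.
#' @examples
#' evalue_point(1.20)   # 1.69 at 2 decimals
#' @export
evalue_point <- function(or_value, rare_outcome = TRUE) {
  if (any(is.na(or_value)) || any(or_value <= 0)) {
    stop("odds ratios must be strictly positive")
  }
  r <- ifelse(or_value < 1, 1 / or_value, or_value)
  if (!rare_outcome) r <- sqrt(r)
  r + sqrt(r * (r - 1))
}

#' E-value for a confidence limit
#'
#' The robustness of the interval: 1 when the confidence interval already
#' contains the null (no unmeasured confounding is needed to reach an OR
#' of 1), otherwise the E-value of the limit closer to 1.
#'
#' @param or_value Point estimate.
#' @param ci_low,ci_high Confidence limits, with
#'   `ci_low <= or_value <= ci_high`.
#' @inheritParams evalue_point
#' @return E-value of the null-closer confidence limit.
#' @examples
#' evalue_ci(1.17, 1.08, 1.26)
#' @export
evalue_ci <- function(or_value, ci_low, ci_high, rare_outcome = TRUE) {
  n <- max(length(or_value), length(ci_low), length(ci_high))
  or_value <- rep_len(or_value, n)
  ci_low <- rep_len(ci_low, n)
  ci_high <- rep_len(ci_high, n)
  if (any(ci_low > ci_high) || any(or_value < ci_low) || any(or_value > ci_high)) {
    stop("confidence limits must satisfy ci_low <= or_value <= ci_high")
  }
  limit <- ifelse(or_value >= 1, ci_low, ci_high)
  out <- ifelse(ci_low <= 1 & ci_high >= 1, 1,
                evalue_point(pmax(limit, .Machine$double.eps),
                             rare_outcome = rare_outcome))
  out
}

#' Attach E-values to an estimate table
#'
#' Adds `evalue` (point estimate) and `evalue_ci` (null-closer confidence
#' limit) columns to a data.frame of effect estimates as produced by
#' [fit_weighted_outcome_model()].
#'
#' @param estimates data.frame with `odds_ratio`, `ci_low`, `ci_high`.
#' @inheritParams evalue_point
#' @return The input with two extra columns.
#' @export
add_evalues <- function(estimates, rare_outcome = TRUE) {
  estimates$evalue <- evalue_point(estimates$odds_ratio, rare_outcome)
  estimates$evalue_ci <- evalue_ci(estimates$odds_ratio, estimates$ci_low,
                                   estimates$ci_high, rare_outcome)
  estimates
}
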