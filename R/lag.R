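#' Build the lagged analysis table
#'
#' Pairs the exposure and time-updated covariates measured at wave `t` with
#' the outcome measured at wave `t + lag_waves`, establishing temporal
#' ordering between exposure and outcome (one-year lag by default). Rows
#' whose outcome wave is censored (dropout, or CES-D-10 not administered)
#' are kept and flagged via `outcome_censored` rather than silently
#' dropped, so the censoring-weight machinery can account for them.
#'
#' @param cohort A [cohort_table()].
#' @param lag_waves Positive integer lag between exposure and outcome waves.
#' @return data.frame with one row per participant-exposure-wave:
#'   `participant_id`, `exposure_wave`, `outcome_wave`, `alcohol_category`
#'   and covariates measured at the exposure wave, and `outcome` (the lagged
#'   `depressed` flag, `NA` when `outcome_censored`).
#' @export
lag_exposure <- function(cohort, lag_waves = 1L) {
  lag_waves <- as.integer(lag_waves)
  if (lag_waves < 1L) stop("lag_waves must be >= 1")
  nw <- n_waves(cohort)
  covs <- unique(unlist(covariate_roles(cohort), use.names = FALSE))
  if (nw < lag_waves + 1L) {
    warning("cohort has fewer than lag_waves + 1 waves; empty analysis table")
    out <- data.frame(participant_id = character(), exposure_wave = integer(),
                      outcome_wave = integer(),
                      alcohol_category = factor(character(), levels = alcohol_levels),
                      outcome = logical(), outcome_censored = logical())
    return(out)
  }
  exp_rows <- cohort[!cohort$censored & cohort$wave <= (nw - 1L - lag_waves) &
                       !is.na(cohort$alcohol_category), , drop = FALSE]
  keep_cols <- c("participant_id", "wave", "alcohol_category", covs)
  keep_cols <- intersect(keep_cols, names(exp_rows))
  out <- as.data.frame(exp_rows)[, keep_cols, drop = FALSE]
  names(out)[names(out) == "wave"] <- "exposure_wave"
  out$outcome_wave <- out$exposure_wave + lag_waves

  okey <- paste(cohort$participant_id, cohort$wave)
  idx <- match(paste(out$participant_id, out$outcome_wave), okey)
  dep <- cohort$depressed[idx]
  cens <- cohort$censored[idx]
  # a wave row can be observed but carry no CES-D (staggered administration):
  # treated as a censored outcome wave
  cens[is.na(cens)] <- TRUE
  cens <- cens | is.na(dep)
  out$outcome <- ifelse(cens, NA, dep)
  out$outcome_censored <- cens
  rownames(out) <- NULL
  out
}
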