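# Small deterministic cohort builders used across the unit tests.

# Hand-built long-format cohort: `categories` has one row per
# participant and one column per wave (category index 1..4);
# `censored_from` gives the wave from which a participant is censored.
manual_cohort <- function(categories, censored_from = NULL, outcomes = NULL,
                          sex = NULL, l = NULL) {
  n <- nrow(categories)
  nw <- ncol(categories)
  censored_from <- censored_from %||% rep(Inf, n)
  sex <- sex %||% rep(c("female", "male"), length.out = n)
  rows <- list()
  for (i in seq_len(n)) {
    for (w in seq_len(nw) - 1L) {
      cens <- w >= censored_from[i]
      cat_i <- categories[i, w + 1L]
      y <- if (is.null(outcomes)) (i + w) %% 11 == 0 else outcomes[i, w + 1L]
      score <- if (isTRUE(y)) 9L else 3L
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = sprintf("T%03d", i), wave = w, censored = cens,
        days_per_week = NA_real_, drinks_per_day = NA_real_,
        heavy_episodic = NA,
        alcohol_category = factor(if (cens) NA else alcohol_levels[cat_i],
                                  levels = alcohol_levels),
        former_drinker = FALSE, sex = sex[i],
        age = 72 + (i %% 9),
        health_burden = if (cens) NA_real_ else
          (if (is.null(l)) (i %% 5) / 5 - 0.4 else l[i, w + 1L]),
        cesd_score = if (cens) NA_integer_ else score,
        depressed = if (cens) NA else y,
        psychotropic = FALSE)
    }
  }
  cohort_table(do.call(rbind, rows),
               baseline_covariates = c("sex", "age"),
               time_updated_covariates = "health_burden")
}

# `%||%` is internal to the package; re-declare for helpers
`%||%` <- function(x, y) if (is.null(x)) y else x

expect_close <- function(object, expected, tol) {
  expect_true(all(abs(object - expected) <= tol),
              label = paste0(deparse(substitute(object)), " = ",
                             paste(signif(object, 4), collapse = ", "),
                             " vs ", paste(signif(expected, 4), collapse = ", ")))
}
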