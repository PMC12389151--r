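#' Construct a long-format longitudinal cohort table
#'
#' A `cohort_table` is a data.frame with one row per participant-wave,
#' carrying exposure reports, CES-D-10 outcome, censoring indicator and
#' covariates, plus metadata describing the wave structure and covariate
#' roles. Wave 0 is baseline; waves are annual. Every participant has a row
#' for every wave up to `n_waves - 1`; waves after dropout are present with
#' `censored = TRUE` and missing measurements, so censoring bookkeeping is
#' explicit.
#'
#' @param data data.frame with at least `participant_id`, `wave`,
#'   `censored`, `alcohol_category`, `cesd_score`, `depressed`.
#' @param baseline_covariates,time_updated_covariates Character vectors of
#'   covariate column names by role. Baseline covariates are constant within
#'   participant; time-updated covariates may change by wave.
#' @param n_waves Number of waves; inferred from the data when `NULL`.
#' @param validate Run [validate_cohort()]?
#' @param strict Passed to [validate_cohort()]: also require non-missing
#'   baseline exposure and outcome (an analysis-ready table).
#' @return A `cohort_table` (data.frame subclass).
#' @seealso [simulate_cohort()], [read_cohort()], [apply_exclusions()]
#' @export
cohort_table <- function(data, baseline_covariates = character(),
                         time_updated_covariates = character(),
                         n_waves = NULL, validate = TRUE, strict = FALSE) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data)
  n_waves <- as.integer(n_waves %||% (max(data$wave) + 1L))
  structure(data,
            class = c("cohort_table", "data.frame"),
            n_waves = n_waves,
            covariate_roles = list(baseline = baseline_covariates,
                                   time_updated = time_updated_covariates)) |>
    (\(x) if (validate) validate_cohort(x, strict = strict) else x)()
}

#' @rdname cohort_table
#' @param x A `cohort_table`.
#' @export
validate_cohort <- function(x, strict = FALSE) {
  required <- c("participant_id", "wave", "censored", "alcohol_category",
                "cesd_score", "depressed")
  miss <- setdiff(required, names(x))
  if (length(miss) > 0L) {
    stop("cohort table is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  }
  covs <- unlist(covariate_roles(x), use.names = FALSE)
  miss <- setdiff(covs, names(x))
  if (length(miss) > 0L) {
    stop("declared covariate column(s) absent: ", paste(miss, collapse = ", "))
  }
  key <- paste(x$participant_id, x$wave)
  if (anyDuplicated(key)) {
    stop("duplicate (participant_id, wave) at row(s): ",
         paste(utils::head(which(duplicated(key))), collapse = ", "))
  }
  if (any(x$wave < 0)) stop("waves must be >= 0")
  base <- x[x$wave == 0L, ]
  ids <- unique(x$participant_id)
  if (!all(ids %in% base$participant_id)) {
    stop("every participant must have a baseline (wave 0) row")
  }
  if (any(base$censored)) stop("wave 0 must not be censored")
  # monotone censoring: once censored, always censored
  ord <- order(x$participant_id, x$wave)
  cs <- x$censored[ord]
  idx <- x$participant_id[ord]
  newp <- c(TRUE, idx[-1L] != idx[-length(idx)])
  uncensor <- !newp & !cs & c(FALSE, cs[-length(cs)])
  if (any(uncensor)) {
    stop("censoring must be monotone (participant re-appears after dropout): ",
         paste(utils::head(unique(idx[uncensor])), collapse = ", "))
  }
  obs <- !x$censored
  if (any(obs & is.na(x$alcohol_category))) {
    stop("observed waves must carry an alcohol category")
  }
  sc <- x$cesd_score[obs & !is.na(x$cesd_score)]
  if (any(sc < 0 | sc > 30)) stop("cesd_score outside 0..30")
  if (strict) {
    if (any(is.na(base$alcohol_category)) || any(is.na(base$depressed))) {
      stop("analysis-ready cohorts require non-missing baseline exposure ",
           "and baseline outcome; run apply_exclusions() first")
    }
  }
  invisible(x)
}

#' @rdname cohort_table
#' @export
covariate_roles <- function(x) {
  attr(x, "covariate_roles") %||% list(baseline = character(),
                                       time_updated = character())
}

#' @rdname cohort_table
#' @export
n_waves <- function(x) attr(x, "n_waves") %||% (max(x$wave) + 1L)

#' @export
print.cohort_table <- function(x, ...) {
  ids <- unique(x$participant_id)
  obs <- sum(!x$censored)
  cat(sprintf("<cohort_table> %d participants x %d waves (%d observed rows)\n",
              length(ids), n_waves(x), obs))
  roles <- covariate_roles(x)
  cat("  baseline covariates:    ",
      paste(roles$baseline, collapse = ", "), "\n", sep = "")
  cat("  time-updated covariates:",
      paste(roles$time_updated, collapse = ", "), "\n", sep = "")
  base <- x[x$wave == 0L, ]
  tab <- table(base$alcohol_category)
  cat("  baseline exposure: ",
      paste(sprintf("%s %.1f%%", names(tab), 100 * tab / sum(tab)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

# subsetting keeps class and metadata
#' @export
`[.cohort_table` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "n_waves") <- attr(x, "n_waves")
    attr(out, "covariate_roles") <- attr(x, "covariate_roles")
    class(out) <- class(x)
  }
  out
}

subset_participants <- function(cohort, keep_ids) {
  out <- cohort[cohort$participant_id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}
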