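#' Configuration for the full analysis pipeline
#'
#' Bundles everything [run_analysis()] needs: the cohort source (a
#' simulation config or a file path), outcome cutoff, which analyses and
#' sensitivity scenarios to run, the weighting options, interaction
#' modifiers, seed and output directory.
#'
#' @param simulation A [sim_config()] (used when `input` is `NULL`).
#' @param input Optional path to a cohort CSV/TSV (see [read_cohort()]).
#' @param cutoff Primary CES-D-10 cutoff (8).
#' @param analyses Subset of `c("PP", "ITT")`; PP is primary.
#' @param scenarios Sensitivity scenarios, any of `"exclude_former"`,
#'   `"exclude_baseline_depressed"`, `"cutoff_10"`.
#' @param modifiers Covariates for interaction analyses (default sex).
#' @param stabilized,cumulative,trim,trim_mode,censoring_covariates,exposure_method
#'   Weighting options, passed through to [run_pp()]/[run_itt()].
#' @param seed Seed recorded in every output (and used for simulation when
#'   no explicit simulation config is given).
#' @param output_dir Optional directory for CSV/markdown outputs.
#' @return An `analysis_config` (classed list).
#' @export
analysis_config <- function(simulation = sim_config(seed = seed),
                            input = NULL,
                            cutoff = 8L,
                            analyses = c("PP", "ITT"),
                            scenarios = c("exclude_former",
                                          "exclude_baseline_depressed",
                                          "cutoff_10"),
                            modifiers = "sex",
                            stabilized = TRUE, cumulative = TRUE,
                            trim = c(0, 100), trim_mode = "exclude",
                            censoring_covariates = "time_updated",
                            exposure_method = "multinomial",
                            seed = 1L,
                            output_dir = NULL) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  known <- c("exclude_former", "exclude_baseline_depressed", "cutoff_10")
  bad <- setdiff(scenarios, known)
  if (length(bad) > 0L) {
    stop("unknown scenario(s): ", paste(bad, collapse = ", "))
  }
  structure(as.list(environment()), class = "analysis_config")
}

#' Run the full analysis pipeline
#'
#' Loads or simulates the cohort, applies the standard exclusions when the
#' relevant flags are present, runs the per-protocol (and optionally
#' intention-to-treat) weighted analyses, the sensitivity scenarios (each
#' re-estimating its weights on its own subset), the interaction analyses,
#' attaches E-values to every estimate, and optionally writes CSV and
#' markdown reports. Deterministic given config, input and seed.
#'
#' @param config An [analysis_config()].
#' @return An `analysis_report`: list with `estimates` (all analysis
#'   blocks, E-values attached), `interactions`, `exclusions`, `balance`,
#'   `weight_summary`, `stage_log` and a `provenance` block (seed, config
#'   hash).
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  log <- list()
  note <- function(stage, ...) {
    log[[length(log) + 1L]] <<- sprintf("[%s] %s", stage, sprintf(...))
  }
  cohort <- if (!is.null(config$input)) read_cohort(config$input)
            else simulate_cohort(config$simulation)
  note("input", "%d participants, %d waves",
       length(unique(cohort$participant_id)), n_waves(cohort))

  excl_report <- NULL
  rules <- c(if (!all(is.na(cohort$cesd_score[cohort$wave == 0]))) "missing_baseline_outcome",
             if ("psychotropic" %in% names(cohort)) "baseline_psychotropic_use")
  if (length(rules) > 0L) {
    ex <- apply_exclusions(cohort, rules, cutoff = config$cutoff)
    cohort <- ex$cohort
    excl_report <- ex$report
    note("exclusions", "retained %d of %d",
         ex$report$n_retained, ex$report$n_input)
  }

  run_one <- function(tag, data, cutoff) {
    if (tag == "PP") {
      run_pp(data, cutoff = cutoff, stabilized = config$stabilized,
             cumulative = config$cumulative,
             censoring_covariates = config$censoring_covariates,
             trim = config$trim, trim_mode = config$trim_mode,
             exposure_method = config$exposure_method)
    } else {
      run_itt(data, cutoff = cutoff, stabilized = config$stabilized,
              censoring_covariates = config$censoring_covariates,
              trim = config$trim, trim_mode = config$trim_mode,
              exposure_method = config$exposure_method)
    }
  }

  blocks <- list()
  main <- list()
  for (tag in config$analyses) {
    main[[tag]] <- run_one(tag, cohort, config$cutoff)
    blocks[[paste0("main_", tag)]] <- main[[tag]]$estimates
    note(tag, "n obs %d, weight band [%.3g, %.3g], %d trimmed",
         main[[tag]]$weighted_fit$n_obs,
         attr(main[[tag]]$weight_set, "cuts")[1L],
         attr(main[[tag]]$weight_set, "cuts")[2L],
         attr(main[[tag]]$weight_set, "n_excluded"))
  }

  sens <- run_sensitivity_suite(cohort, config)
  for (nm in names(sens)) blocks[[nm]] <- sens[[nm]]$estimates
  note("sensitivity", "%d scenario(s)", length(sens))

  interactions <- list()
  pp_main <- main[["PP"]] %||% main[[1L]]
  for (mod in config$modifiers) {
    if (mod %in% names(pp_main$analysis)) {
      interactions[[mod]] <- fit_interaction(pp_main$analysis,
                                             weights = pp_main$weights,
                                             modifier = mod)
    }
  }

  estimates <- do.call(rbind, lapply(names(blocks), function(nm) {
    df <- blocks[[nm]]
    df$block <- nm
    df
  }))
  rownames(estimates) <- NULL
  estimates <- add_evalues(estimates)

  report <- structure(
    list(estimates = estimates,
         interactions = interactions,
         exclusions = excl_report,
         balance = pp_main$balance,
         weight_summary = list(cuts = attr(pp_main$weight_set, "cuts"),
                               n_excluded = attr(pp_main$weight_set, "n_excluded"),
                               quartiles = summary(pp_main$weight_set$combined)),
         analyses = main,
         sensitivity = sens,
         stage_log = unlist(log),
         provenance = list(seed = config$seed,
                           config_hash = config_hash(unclass(config)),
                           package_version = as.character(utils::packageVersion("jshape")))),
    class = "analysis_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' Run the sensitivity scenarios
#'
#' Scenario 1 (`exclude_former`) drops baseline former drinkers before any
#' weighting; scenario 2 (`exclude_baseline_depressed`) drops participants
#' with baseline CES-D-10 at or above 8; scenario 3 (`cutoff_10`)
#' re-dichotomises the outcome at 10. Each scenario re-estimates its
#' weights on its own subset, defining its own pseudo-population.
#'
#' @param cohort Analysis-ready [cohort_table()].
#' @param config An [analysis_config()] (its `scenarios` field selects the
#'   scenarios; the primary analysis listed first in `analyses` is re-run).
#' @return Named list of `msm_analysis` objects, one per scenario.
#' @export
run_sensitivity_suite <- function(cohort, config) {
  tag <- config$analyses[1L]
  out <- list()
  for (sc in config$scenarios) {
    sub <- cohort
    cutoff <- config$cutoff
    if (sc == "exclude_former") {
      sub <- apply_exclusions(cohort, "former_drinker")$cohort
    } else if (sc == "exclude_baseline_depressed") {
      sub <- apply_exclusions(cohort, "baseline_depressed", cutoff = 8L)$cohort
    } else if (sc == "cutoff_10") {
      cutoff <- 10L
    }
    if (length(unique(sub$participant_id)) == 0L) {
      stop("scenario '", sc, "' removed every participant")
    }
    res <- if (tag == "PP") {
      run_pp(sub, cutoff = cutoff, stabilized = config$stabilized,
             cumulative = config$cumulative,
             censoring_covariates = config$censoring_covariates,
             trim = config$trim, trim_mode = config$trim_mode,
             exposure_method = config$exposure_method, balance = FALSE)
    } else {
      run_itt(sub, cutoff = cutoff, stabilized = config$stabilized,
              censoring_covariates = config$censoring_covariates,
              trim = config$trim, trim_mode = config$trim_mode,
              exposure_method = config$exposure_method, balance = FALSE)
    }
    res$estimates$analysis <- paste0(sc, "_", res$estimates$analysis)
    out[[sc]] <- res
  }
  out
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$estimates, file.path(dir, "estimates.csv"),
                   row.names = FALSE)
  if (!is.null(report$balance)) {
    utils::write.csv(as.data.frame(report$balance),
                     file.path(dir, "balance.csv"), row.names = FALSE)
  }
  md <- c("# Analysis report", "",
          sprintf("Seed: %d; config hash: %s; jshape %s",
                  report$provenance$seed, report$provenance$config_hash,
                  report$provenance$package_version), "",
          "## Effect estimates", "",
          format_estimates_markdown(report$estimates), "")
  if (!is.null(report$balance)) {
    md <- c(md, "## Covariate balance", "",
            format_balance_markdown(report$balance), "")
  }
  md <- c(md, "## Stage log", "", paste0("- ", report$stage_log))
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}

format_estimates_markdown <- function(est) {
  c("| Block | Contrast | OR | 95% CI | E-value | E-value (CI) | p |",
    "|---|---|---|---|---|---|---|",
    sprintf("| %s | %s | %.2f | %.2f-%.2f | %.2f | %.2f | %.3g |",
            est$block, est$contrast, est$odds_ratio, est$ci_low, est$ci_high,
            est$evalue, est$evalue_ci, est$p_value))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  for (line in x$stage_log) cat(" ", line, "\n")
  df <- x$estimates
  cat(sprintf("  %-34s %-30s %6s  [%5s,%5s]  E\n",
              "block", "contrast", "OR", "lo", "hi"))
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-34s %-30s %6.3f  [%5.3f,%5.3f]  %.2f\n",
                df$block[i], df$contrast[i], df$odds_ratio[i],
                df$ci_low[i], df$ci_high[i], df$evalue[i]))
  }
  invisible(x)
}

#' Simulation-based power for an exposure-by-sex interaction
#'
#' Estimates the power of the weighted interaction analysis to detect a
#' multiplicative shift of the female odds ratios by `1 + delta`, by
#' simulating replicate cohorts with the interaction injected into the
#' generating model, running the per-protocol pipeline and the joint Wald
#' interaction test, and reporting the rejection fraction at `alpha` with
#' a binomial Monte-Carlo confidence interval. With `delta = 0` the power
#' estimate is the test's size. This is a generic calculator: its
#' assumptions are whatever the supplied simulation config encodes.
#'
#' @param config A [sim_config()] describing the cohorts to simulate.
#' @param effect_delta_pct Percent change in OR for females (16 means the
#'   female ORs are multiplied by 1.16).
#' @param alpha Test level.
#' @param n_replicates Number of simulated cohorts (at least 100).
#' @param seed Seed controlling the replicate seeds.
#' @return List with `power`, `mc_ci` (95% binomial), `alpha`,
#'   `n_replicates`, `effect_delta_pct`.
#' @export
power_by_simulation <- function(config, effect_delta_pct, alpha = 0.05,
                                n_replicates = 200L, seed = 1L) {
  if (n_replicates < 100L) stop("n_replicates must be at least 100")
  delta <- log(1 + effect_delta_pct / 100)
  reject <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- seed * 10000L + r
    cfg$sex_interaction_log_or <- c(delta, delta, 0, delta)
    cohort <- simulate_cohort(cfg)
    pp <- run_pp(cohort, balance = FALSE)
    int <- fit_interaction(pp$analysis, weights = pp$weights, modifier = "sex")
    reject[r] <- int$joint_p < alpha
  }
  power <- mean(reject)
  se <- sqrt(power * (1 - power) / n_replicates)
  list(power = power,
       mc_ci = c(max(0, power - 1.96 * se), min(1, power + 1.96 * se)),
       alpha = alpha, n_replicates = n_replicates,
       effect_delta_pct = effect_delta_pct)
}
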