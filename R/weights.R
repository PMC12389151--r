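#' Fit the exposure (propensity) model for the four categories
#'
#' Estimates each observed row's probability of belonging to every alcohol
#' category given covariates. Two submodels are fitted: a baseline model
#' (wave 0, covariates only) and a follow-up model (previous wave's
#' category, covariates, and wave indicators), reflecting the sequential
#' treatment-assignment mechanism. The default `"multinomial"` method fits
#' multinomial logistic regressions, whose predicted probabilities sum to 1
#' by construction. The `"one_vs_rest"` method instead fits one binary
#' logistic model per category and renormalises the four probabilities,
#' recording the pre-normalisation sums as a model-agreement diagnostic.
#'
#' @param cohort A [cohort_table()].
#' @param covariates Covariate columns to use; defaults to every declared
#'   baseline and time-updated covariate. Constant columns are dropped with
#'   a message.
#' @param method `"multinomial"` (default) or `"one_vs_rest"`.
#' @return An `exposure_fit`: list with `index` (participant/wave of each
#'   scored row), `probabilities` (n x 4 matrix), `p_observed` (probability
#'   of the category actually observed), the fitted `models`, and for
#'   one-vs-rest the `prenorm_sums`.
#' @export
fit_exposure_model <- function(cohort, covariates = NULL,
                               method = c("multinomial", "one_vs_rest")) {
  method <- match.arg(method)
  roles <- covariate_roles(cohort)
  covariates <- covariates %||% unique(unlist(roles, use.names = FALSE))
  if ("alcohol_category" %in% covariates) {
    stop("the exposure cannot predict itself at the same wave")
  }
  miss <- setdiff(covariates, names(cohort))
  if (length(miss) > 0L) stop("unknown covariate(s): ", paste(miss, collapse = ", "))
  obs <- as.data.frame(cohort[!cohort$censored & !is.na(cohort$alcohol_category), ,
                              drop = FALSE])
  if (anyNA(obs[, covariates, drop = FALSE])) {
    stop("missing covariate values among observed rows; resolve upstream")
  }
  obs <- obs[order(obs$participant_id, obs$wave), , drop = FALSE]
  # previous wave's category (defined for every observed follow-up wave,
  # censoring being monotone)
  key <- paste(obs$participant_id, obs$wave)
  prev_idx <- match(paste(obs$participant_id, obs$wave - 1L), key)
  obs$prev_category <- obs$alcohol_category[prev_idx]

  fit_part <- function(rows, rhs_vars) {
    dat <- obs[rows, c("alcohol_category", rhs_vars), drop = FALSE]
    keep <- vapply(rhs_vars, function(v) length(unique(dat[[v]])) > 1L, logical(1))
    if (any(!keep)) {
      message("dropping constant predictor(s): ",
              paste(rhs_vars[!keep], collapse = ", "))
    }
    rhs <- if (any(keep)) paste(rhs_vars[keep], collapse = " + ") else "1"
    form <- stats::as.formula(paste("alcohol_category ~", rhs))
    if (method == "multinomial") {
      fit <- nnet::multinom(form, data = dat, trace = FALSE, maxit = 500)
      if (fit$convergence != 0) {
        stop("multinomial exposure model failed to converge (predictors: ",
             rhs, "); check for separation")
      }
      pr <- stats::predict(fit, newdata = dat, type = "probs")
      if (is.null(dim(pr))) pr <- rbind(pr)   # single-row edge
      list(prob = pr[, alcohol_levels, drop = FALSE], fit = fit, prenorm = NULL)
    } else {
      raw <- sapply(alcohol_levels, function(lev) {
        f <- stats::as.formula(paste("I(alcohol_category == lev) ~", rhs))
        g <- stats::glm(f, data = dat, family = stats::binomial())
        if (!g$converged) {
          stop("one-vs-rest exposure model for '", lev,
               "' failed to converge (predictors: ", rhs, ")")
        }
        stats::predict(g, type = "response")
      })
      sums <- rowSums(raw)
      list(prob = raw / sums, fit = NULL, prenorm = sums)
    }
  }

  prob <- matrix(NA_real_, nrow(obs), 4L,
                 dimnames = list(NULL, alcohol_levels))
  prenorm <- rep(NA_real_, nrow(obs))
  models <- list()
  base_rows <- which(obs$wave == 0L)
  if (length(base_rows) > 0L) {
    part <- fit_part(base_rows, covariates)
    prob[base_rows, ] <- part$prob
    if (!is.null(part$prenorm)) prenorm[base_rows] <- part$prenorm
    models$baseline <- part$fit
  }
  fup_rows <- which(obs$wave > 0L & !is.na(obs$prev_category))
  if (length(fup_rows) > 0L) {
    obs$wave_f <- factor(obs$wave)
    rhs_vars <- c("prev_category", covariates,
                  if (length(unique(obs$wave[fup_rows])) > 1L) "wave_f")
    part <- fit_part(fup_rows, rhs_vars)
    prob[fup_rows, ] <- part$prob
    if (!is.null(part$prenorm)) prenorm[fup_rows] <- part$prenorm
    models$followup <- part$fit
  }
  p_obs <- prob[cbind(seq_len(nrow(obs)), as.integer(obs$alcohol_category))]
  structure(list(index = data.frame(participant_id = obs$participant_id,
                                    wave = obs$wave),
                 observed_category = obs$alcohol_category,
                 probabilities = prob,
                 p_observed = p_obs,
                 prenorm_sums = if (method == "one_vs_rest") prenorm,
                 models = models,
                 method = method,
                 covariates = covariates),
            class = "exposure_fit")
}

#' Inverse probability of treatment weights
#'
#' The base weight of an observation is the reciprocal of the modelled
#' probability of its observed category. Stabilised weights multiply by a
#' numerator probability of the observed category: either the per-wave
#' marginal category frequency (`numerator = "marginal"`, sample mean 1 in
#' expectation) or, for persistent time-varying exposures, the probability
#' conditional on the previous wave's category (`numerator = "history"`,
#' the standard sequential stabilisation, which keeps cumulative products
#' close to 1 when most participants repeat their category). Cumulative
#' weights take the running product over waves within participant, as
#' appropriate for a time-varying treatment.
#'
#' @param probabilities n x 4 matrix of category probabilities (or an
#'   `exposure_fit`, from which everything else is taken).
#' @param observed_category Factor of observed categories (one per row).
#' @param stabilized Multiply by a numerator category probability?
#' @param cumulative Running product over waves within participant?
#' @param numerator `"marginal"` (default) or `"history"` (needs an
#'   `exposure_fit` or `participant_id`/`wave`, to locate the previous
#'   category).
#' @param participant_id,wave Row identifiers; required when `cumulative`.
#' @return data.frame `participant_id`, `wave`, `iptw`.
#' @export
compute_iptw <- function(probabilities, observed_category = NULL,
                         stabilized = FALSE, cumulative = TRUE,
                         numerator = c("marginal", "history"),
                         participant_id = NULL, wave = NULL) {
  numerator <- match.arg(numerator)
  if (inherits(probabilities, "exposure_fit")) {
    fit <- probabilities
    probabilities <- fit$probabilities
    observed_category <- observed_category %||% fit$observed_category
    participant_id <- participant_id %||% fit$index$participant_id
    wave <- wave %||% fit$index$wave
  }
  n <- nrow(probabilities)
  p_obs <- probabilities[cbind(seq_len(n), as.integer(observed_category))]
  floor_p <- .Machine$double.eps
  bad <- which(p_obs <= floor_p | p_obs >= 1)
  if (length(bad) > 0L) {
    stop("treatment probabilities at or below machine floor (or >= 1) for ",
         length(bad), " row(s), e.g. rows ",
         paste(utils::head(bad), collapse = ", "))
  }
  w <- 1 / p_obs
  if (stabilized) {
    wv <- wave %||% rep(0L, n)
    num <- numerator_probs(observed_category, wv, participant_id, numerator)
    w <- w * num
  }
  if (cumulative) {
    if (is.null(participant_id) || is.null(wave)) {
      stop("cumulative weights need participant_id and wave")
    }
    ord <- order(participant_id, wave)
    w_o <- w[ord]
    cum <- stats::ave(w_o, participant_id[ord], FUN = cumprod)
    w[ord] <- cum
  }
  data.frame(participant_id = participant_id %||% seq_len(n),
             wave = wave %||% rep(0L, n), iptw = w)
}

# numerator probability of the observed category for stabilised weights:
# per-wave marginal frequencies, or (for follow-up waves) frequencies
# conditional on the previous wave's category
numerator_probs <- function(observed_category, wave, participant_id,
                            numerator) {
  n <- length(observed_category)
  levs <- levels(observed_category)
  out <- numeric(n)
  marg_for <- function(rows) {
    marg <- prop.table(table(factor(observed_category[rows], levels = levs)))
    as.numeric(marg[as.integer(observed_category[rows])])
  }
  if (numerator == "marginal" || is.null(participant_id)) {
    for (wval in unique(wave)) {
      rows <- which(wave == wval)
      out[rows] <- marg_for(rows)
    }
    return(out)
  }
  key <- paste(participant_id, wave)
  prev <- observed_category[match(paste(participant_id, wave - 1L), key)]
  base <- which(is.na(prev))
  for (wval in unique(wave[base])) {
    rows <- base[wave[base] == wval]
    out[rows] <- marg_for(rows)
  }
  fup <- which(!is.na(prev))
  for (wval in unique(wave[fup])) {
    for (pc in levs) {
      rows <- fup[wave[fup] == wval & prev[fup] == pc]
      if (length(rows) > 0L) out[rows] <- marg_for(rows)
    }
  }
  out
}

#' Fit the censoring (follow-up participation) model
#'
#' Among participants under follow-up at wave `s - 1`, models the
#' probability of remaining observed at wave `s` by pooled logistic
#' regression with wave indicators. Predictors are either the covariates
#' measured at the previous wave (`"time_updated"`, including the previous
#' category -- the correctly specified choice when dropout depends on
#' evolving health) or the baseline values only (`"baseline"`). Waves with
#' no dropout events contribute retention probability 1 and are excluded
#' from the fit.
#'
#' @param cohort A [cohort_table()].
#' @param covariates `"time_updated"` or `"baseline"`.
#' @return A `censoring_fit`: data.frame `participant_id`, `wave`,
#'   `p_retain` for every at-risk row, with the fitted `model` and the
#'   no-event waves in attributes.
#' @export
fit_censoring_model <- function(cohort, covariates = c("time_updated", "baseline")) {
  covariates <- match.arg(covariates)
  roles <- covariate_roles(cohort)
  covs <- unique(unlist(roles, use.names = FALSE))
  nw <- n_waves(cohort)
  df <- as.data.frame(cohort)
  key <- paste(df$participant_id, df$wave)
  base <- df[df$wave == 0L, , drop = FALSE]
  bkey <- base$participant_id

  risk <- do.call(rbind, lapply(seq_len(nw - 1L), function(s) {
    prev <- df[df$wave == s - 1L & !df$censored, , drop = FALSE]
    cur_cens <- df$censored[match(paste(prev$participant_id, s), key)]
    src <- if (covariates == "time_updated") prev else
      base[match(prev$participant_id, bkey), , drop = FALSE]
    out <- src[, c(covs, "alcohol_category"), drop = FALSE]
    out$participant_id <- prev$participant_id
    out$wave <- s
    out$retained <- !(cur_cens %in% TRUE)
    out
  }))
  ev <- tapply(!risk$retained, risk$wave, sum)
  no_event_waves <- as.integer(names(ev)[ev == 0])
  fit_rows <- !(risk$wave %in% no_event_waves)
  p <- rep(1, nrow(risk))
  model <- NULL
  if (any(fit_rows)) {
    dat <- risk[fit_rows, , drop = FALSE]
    dat$wave_f <- factor(dat$wave)
    rhs_vars <- c(covs, "alcohol_category",
                  if (length(unique(dat$wave)) > 1L) "wave_f")
    keep <- vapply(rhs_vars, function(v) length(unique(dat[[v]])) > 1L, logical(1))
    rhs <- if (any(keep)) paste(rhs_vars[keep], collapse = " + ") else "1"
    model <- stats::glm(stats::as.formula(paste("retained ~", rhs)),
                        data = dat, family = stats::binomial())
    p[fit_rows] <- stats::predict(model, type = "response")
  }
  if (length(no_event_waves) > 0L) {
    message("no censoring events at wave(s) ",
            paste(no_event_waves, collapse = ", "), "; retention set to 1")
  }
  structure(data.frame(participant_id = risk$participant_id,
                       wave = risk$wave, p_retain = p),
            model = model, no_event_waves = no_event_waves,
            class = c("censoring_fit", "data.frame"))
}

#' Inverse probability of censoring weights
#'
#' Reciprocal of the retention probability, cumulated over waves within
#' participant by default: the weight at wave `s` is
#' `1 / prod(p_retain[1..s])`, which is always at least 1.
#'
#' @param retention A `censoring_fit` (or data.frame with
#'   `participant_id`, `wave`, `p_retain`).
#' @param cumulative Cumulate the product over waves (default)?
#' @return data.frame `participant_id`, `wave`, `ipcw`.
#' @export
compute_ipcw <- function(retention, cumulative = TRUE) {
  p <- retention$p_retain
  if (any(p <= .Machine$double.eps | p > 1)) {
    stop("retention probabilities must lie in (0, 1]; offending rows: ",
         paste(utils::head(which(p <= .Machine$double.eps | p > 1)), collapse = ", "))
  }
  w <- 1 / p
  if (cumulative) {
    ord <- order(retention$participant_id, retention$wave)
    w_o <- w[ord]
    w[ord] <- stats::ave(w_o, retention$participant_id[ord], FUN = cumprod)
  }
  data.frame(participant_id = retention$participant_id,
             wave = retention$wave, ipcw = w)
}

#' Combine treatment and censoring weights and trim the tails
#'
#' The final weight of an observation is `iptw * ipcw`. To guard against
#' extreme weights, observations outside the 2nd--98th percentile band of
#' the combined weight distribution are excluded by default (`mode =
#' "exclude"`); `mode = "cap"` winsorises at the band instead, preserving
#' the row count. Percentiles are nearest-rank on the pooled analysis rows,
#' computed once per dataset: with `n` rows, the lowest and highest
#' `floor(n * pct / 100)` observations fall outside the band. Trimming at
#' the (0, 100) percentiles is the identity, and a degenerate all-equal
#' weight distribution excludes nothing.
#'
#' @param iptw,ipcw Aligned weight vectors.
#' @param lower_pct,upper_pct Percentile band (defaults 2 and 98).
#' @param mode `"exclude"` (drop rows, the default) or `"cap"` (winsorise).
#' @return A `weight_set` data.frame: `iptw`, `ipcw`, `combined` (pre-trim
#'   value), `weight` (post-trim: capped, or `NA` for excluded rows) and
#'   `trimmed`, with the cut values and exclusion count in attributes.
#' @export
combine_and_trim <- function(iptw, ipcw, lower_pct = 2, upper_pct = 98,
                             mode = c("exclude", "cap")) {
  mode <- match.arg(mode)
  stopifnot(length(iptw) == length(ipcw))
  combined <- iptw * ipcw
  n <- length(combined)
  srt <- sort(combined)
  k_lo <- floor(n * lower_pct / 100)
  k_hi <- floor(n * (100 - upper_pct) / 100)
  lo_cut <- srt[k_lo + 1L]           # smallest retained value
  hi_cut <- srt[n - k_hi]            # largest retained value
  out_of_band <- combined < lo_cut | combined > hi_cut
  if (mode == "exclude") {
    weight <- ifelse(out_of_band, NA_real_, combined)
    trimmed <- out_of_band
  } else {
    weight <- pmin(pmax(combined, lo_cut), hi_cut)
    trimmed <- rep(FALSE, n)
  }
  structure(data.frame(iptw = iptw, ipcw = ipcw, combined = combined,
                       weight = weight, trimmed = trimmed),
            cuts = c(lower = lo_cut, upper = hi_cut),
            n_excluded = sum(out_of_band),
            mode = mode,
            percentiles = c(lower_pct, upper_pct),
            class = c("weight_set", "data.frame"))
}

#' @export
print.weight_set <- function(x, ...) {
  cuts <- attr(x, "cuts")
  cat(sprintf("<weight_set> %d observations, %d outside [%.3g, %.3g] (%s mode)\n",
              nrow(x), attr(x, "n_excluded"), cuts[1L], cuts[2L], attr(x, "mode")))
  print(summary(x$combined))
  invisible(x)
}
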