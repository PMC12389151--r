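#' Standardized mean difference between two groups
#'
#' `SMD = (m1 - m2) / sqrt((v1 + v2) / 2)` with optionally weighted means
#' and variances. Binary covariates use the proportion variance
#' `p * (1 - p)`. A covariate with zero pooled variance has SMD 0 when the
#' group means agree and is an error otherwise.
#'
#' @param values Numeric (or logical) covariate values.
#' @param group Logical mask: `TRUE` = first group, `FALSE` = second.
#' @param weights Optional non-negative weights.
#' @return The (weighted) standardized mean difference.
#' @export
standardized_mean_difference <- function(values, group, weights = NULL) {
  group <- as.logical(group)
  values <- as.numeric(values)
  if (!any(group) || !any(!group)) stop("both groups must be non-empty")
  w1 <- if (is.null(weights)) NULL else weights[group]
  w2 <- if (is.null(weights)) NULL else weights[!group]
  m1 <- wmean(values[group], w1); m2 <- wmean(values[!group], w2)
  if (is_binary01(values)) {
    v1 <- m1 * (1 - m1); v2 <- m2 * (1 - m2)
  } else {
    v1 <- wvar(values[group], w1); v2 <- wvar(values[!group], w2)
  }
  pooled <- sqrt((v1 + v2) / 2)
  if (pooled == 0) {
    if (isTRUE(all.equal(m1, m2))) return(0)
    stop("zero pooled variance with unequal means")
  }
  (m1 - m2) / pooled
}

#' Covariate balance report by exposure contrast
#'
#' Computes the standardized mean difference of every covariate for each
#' category-versus-moderate contrast, before and after weighting, and flags
#' contrasts with `|SMD| >= 0.10` (the conventional adequacy threshold).
#' Factor and character covariates are expanded into indicator columns.
#'
#' @param analysis Analysis table from [lag_exposure()] (or any data.frame
#'   with `alcohol_category` and the covariates).
#' @param weights Optional weights aligned with `analysis` rows (e.g. the
#'   `weight` column of a [combine_and_trim()] result); rows with `NA`
#'   weight (trimmed) are dropped from the weighted columns.
#' @param covariates Covariate column names to assess.
#' @param reference Reference category (default moderate).
#' @param strata Optional stratification vector (or column name), usually
#'   the exposure wave: SMDs are computed within stratum and combined by
#'   stratum size. Pooling waves would confound drift in the category mix
#'   across waves with genuine covariate imbalance.
#' @return A `balance_report` data.frame: `covariate`, `contrast`,
#'   `smd_unweighted`, `smd_weighted`, `flag_unweighted`, `flag_weighted`.
#' @export
balance_report <- function(analysis, weights = NULL, covariates,
                           reference = "moderate", strata = NULL) {
  stopifnot(all(covariates %in% names(analysis)))
  if (is.character(strata) && length(strata) == 1L && strata %in% names(analysis)) {
    strata <- analysis[[strata]]
  }
  if (!is.null(strata)) {
    stopifnot(length(strata) == nrow(analysis))
    parts <- lapply(split(seq_len(nrow(analysis)), strata), function(rows) {
      rep <- balance_report(analysis[rows, , drop = FALSE],
                            weights = if (is.null(weights)) NULL else weights[rows],
                            covariates = covariates, reference = reference)
      rep$n <- length(rows)
      rep
    })
    all <- do.call(rbind, parts)
    agg <- function(col) {
      ok <- !is.na(all[[col]])
      stats::aggregate(cbind(v = (all[[col]] * all$n)[ok], n = all$n[ok]),
                       by = list(covariate = all$covariate[ok],
                                 contrast = all$contrast[ok]), FUN = sum)
    }
    u <- agg("smd_unweighted")
    out <- data.frame(covariate = u$covariate, contrast = u$contrast,
                      smd_unweighted = u$v / u$n)
    if (!is.null(weights)) {
      w <- agg("smd_weighted")
      idx <- match(paste(out$covariate, out$contrast),
                   paste(w$covariate, w$contrast))
      out$smd_weighted <- (w$v / w$n)[idx]
    } else {
      out$smd_weighted <- NA_real_
    }
    out$flag_unweighted <- abs(out$smd_unweighted) >= 0.10
    out$flag_weighted <- !is.na(out$smd_weighted) & abs(out$smd_weighted) >= 0.10
    class(out) <- c("balance_report", "data.frame")
    return(out)
  }
  cat_col <- analysis$alcohol_category
  # expand non-numeric covariates into indicators
  cols <- list()
  for (cv in covariates) {
    x <- analysis[[cv]]
    if (is.numeric(x) || is.logical(x)) {
      cols[[cv]] <- as.numeric(x)
    } else {
      x <- as.factor(x)
      for (lev in levels(x)[-1L]) {
        cols[[paste0(cv, ":", lev)]] <- as.numeric(x == lev)
      }
    }
  }
  contrasts <- setdiff(alcohol_levels, reference)
  rows <- list()
  for (ct in contrasts) {
    sel <- cat_col %in% c(ct, reference)
    g <- cat_col[sel] == ct
    w <- if (is.null(weights)) NULL else weights[sel]
    keep <- if (is.null(w)) rep(TRUE, sum(sel)) else !is.na(w)
    for (nm in names(cols)) {
      v <- cols[[nm]][sel]
      try_smd <- function(...) tryCatch(standardized_mean_difference(...),
                                        error = function(e) NA_real_)
      smd_u <- try_smd(v, g)
      smd_w <- if (is.null(w)) NA_real_ else try_smd(v[keep], g[keep], w[keep])
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = nm, contrast = paste(ct, "vs", reference),
        smd_unweighted = smd_u, smd_weighted = smd_w)
    }
  }
  out <- do.call(rbind, rows)
  out$flag_unweighted <- abs(out$smd_unweighted) >= 0.10
  out$flag_weighted <- !is.na(out$smd_weighted) & abs(out$smd_weighted) >= 0.10
  class(out) <- c("balance_report", "data.frame")
  out
}

#' @export
print.balance_report <- function(x, digits = 3, ...) {
  cat("<balance_report> standardized mean differences",
      "(|SMD| >= 0.10 flagged *)\n")
  ord <- order(-abs(x$smd_unweighted))   # Love-plot ordering
  df <- x[ord, , drop = FALSE]
  cat(sprintf("  %-24s %-28s %10s %10s\n", "covariate", "contrast",
              "unweighted", "weighted"))
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-24s %-28s %9.3f%s %9.3f%s\n",
                df$covariate[i], df$contrast[i],
                df$smd_unweighted[i], ifelse(df$flag_unweighted[i], "*", " "),
                df$smd_weighted[i], ifelse(df$flag_weighted[i], "*", " ")))
  }
  invisible(x)
}

#' @rdname balance_report
#' @param x A `balance_report`.
#' @return `format_balance_markdown()` returns a character vector of
#'   markdown table lines, ordered by decreasing unweighted imbalance.
#' @export
format_balance_markdown <- function(x) {
  ord <- order(-abs(x$smd_unweighted))
  df <- x[ord, , drop = FALSE]
  c("| Covariate | Contrast | SMD (unweighted) | SMD (weighted) |",
    "|---|---|---|---|",
    sprintf("| %s | %s | %.3f%s | %.3f%s |",
            df$covariate, df$contrast,
            df$smd_unweighted, ifelse(df$flag_unweighted, " *", ""),
            df$smd_weighted, ifelse(df$flag_weighted, " *", "")))
}
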