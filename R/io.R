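#' Read and write cohort tables
#'
#' Cohort tables are stored as plain UTF-8 CSV/TSV with a header plus a JSON
#' sidecar (`<path-without-extension>.json`) recording the wave count,
#' covariate roles, and column classes, so that a write/read round trip is
#' lossless for every field including logicals and missing values. Numeric
#' columns are written with 17 significant digits, enough to reconstruct the
#' binary double exactly.
#'
#' @param path File path. The sidecar lives next to it with extension
#'   `.json`.
#' @param dialect `"csv"` (default) or `"tsv"`.
#' @return `read_cohort()` returns a [cohort_table()]; `write_cohort()`
#'   returns `path` invisibly.
#' @export
read_cohort <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE) else NULL

  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          na.strings = "", stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE,
                          fileEncoding = "UTF-8")
  required <- c("participant_id", "wave")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L) {
    stop("cohort file ", path, " is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  }
  classes <- meta$column_classes
  for (nm in names(df)) {
    cl <- if (!is.null(classes) && nm %in% names(classes)) classes[[nm]] else guess_class(df[[nm]])
    df[[nm]] <- switch(cl,
                       integer = as.integer(df[[nm]]),
                       numeric = as.numeric(df[[nm]]),
                       logical = as.logical(df[[nm]]),
                       factor = factor(df[[nm]], levels = alcohol_levels),
                       df[[nm]])
  }
  key <- paste(df$participant_id, df$wave)
  if (anyDuplicated(key)) {
    stop("duplicate (participant_id, wave) in ", path, " at data row(s): ",
         paste(utils::head(which(duplicated(key))), collapse = ", "))
  }
  cohort_table(df,
               baseline_covariates = as.character(meta$covariate_roles$baseline %||% character()),
               time_updated_covariates = as.character(meta$covariate_roles$time_updated %||% character()),
               n_waves = meta$n_waves %||% NULL)
}

#' @rdname read_cohort
#' @param cohort A [cohort_table()].
#' @export
write_cohort <- function(cohort, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  df <- as.data.frame(cohort)
  classes <- vapply(df, function(col) {
    if (is.factor(col)) "factor"
    else if (is.logical(col)) "logical"
    else if (is.integer(col)) "integer"
    else if (is.numeric(col)) "numeric"
    else "character"
  }, character(1))
  out <- df
  for (nm in names(out)) {
    if (classes[[nm]] == "numeric") {
      v <- sprintf("%.17g", out[[nm]])
      v[is.na(out[[nm]])] <- NA_character_
      out[[nm]] <- v
    } else {
      out[[nm]] <- as.character(out[[nm]])
    }
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, na = "",
                     quote = TRUE, fileEncoding = "UTF-8")
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(list(n_waves = n_waves(cohort),
                            covariate_roles = covariate_roles(cohort),
                            column_classes = as.list(classes),
                            sex_coding = c("male", "female")),
                       sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

guess_class <- function(x) {
  v <- x[!is.na(x)]
  if (length(v) == 0L) return("character")
  if (all(v %in% c("TRUE", "FALSE"))) return("logical")
  if (all(v %in% alcohol_levels)) return("factor")
  suppressWarnings(num <- as.numeric(v))
  if (any(is.na(num))) return("character")
  if (all(num == round(num)) && max(abs(num)) < .Machine$integer.max) return("integer")
  "numeric"
}
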