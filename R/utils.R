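`%||%` <- function(x, y) if (is.null(x)) y else x

#' Exposure category levels
#'
#' Canonical ordering of the four alcohol-consumption categories. The
#' moderate category is the reference in all effect estimates.
#'
#' @format Character vector of length 4.
#' @export
alcohol_levels <- c("abstainer", "occasional", "moderate", "above_guideline")

# weighted mean with frequency-type weights
wmean <- function(x, w = NULL) {
  if (is.null(w)) return(mean(x))
  sum(w * x) / sum(w)
}

# weighted variance (denominator sum of weights, adequate for balance
# diagnostics at the sample sizes involved)
wvar <- function(x, w = NULL) {
  m <- wmean(x, w)
  if (is.null(w)) return(mean((x - m)^2))
  sum(w * (x - m)^2) / sum(w)
}

is_binary01 <- function(x) {
  ux <- unique(x[!is.na(x)])
  all(ux %in% c(0, 1))
}

# deterministic fingerprint of an R object (provenance stamping)
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}
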