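#' Score the CES-D-10 depression screen
#'
#' Computes the total score of the 10-item Center for Epidemiologic Studies
#' Depression short scale. Each item is rated 0--3 for symptom frequency over
#' the past week; positive-mood items are reverse-coded (`3 - value`) before
#' summing, so the total ranges from 0 to 30.
#'
#' @param items Integer vector of length 10 (one respondent), or a numeric
#'   matrix with 10 columns (one respondent per row). Values must be in
#'   `0:3`. Missing values are not imputed: any `NA` yields an `NA` total.
#' @param reverse_positions 1-based positions of the reverse-coded items.
#'   Defaults to items 5 and 8, the two positive-mood items ("felt hopeful
#'   about the future", "was happy") of the standard 10-item short form.
#'
#' @return Integer total score(s) in `0:30` (`NA` where any item is missing).
#' @examples
#' score_cesd10(c(1, 0, 2, 0, 3, 0, 1, 3, 0, 0))
#' @export
score_cesd10 <- function(items, reverse_positions = c(5L, 8L)) {
  if (!is.matrix(items)) {
    items <- matrix(items, nrow = 1L)
    scalar <- TRUE
  } else {
    scalar <- FALSE
  }
  if (ncol(items) != 10L) {
    stop("CES-D-10 requires exactly 10 items, got ", ncol(items))
  }
  bad <- which(!is.na(items) & (items < 0 | items > 3 | items != round(items)),
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("CES-D-10 item out of range 0..3 at position ", bad[1L, 2L],
         " (respondent ", bad[1L, 1L], "): value ",
         items[bad[1L, , drop = FALSE]])
  }
  if (length(reverse_positions) > 0L) {
    reverse_positions <- as.integer(reverse_positions)
    if (any(reverse_positions < 1L | reverse_positions > 10L)) {
      stop("reverse_positions must be within 1..10")
    }
    items[, reverse_positions] <- 3L - items[, reverse_positions]
  }
  total <- as.integer(round(rowSums(items)))
  if (scalar) total[1L] else total
}

#' Dichotomise a CES-D-10 score into probable depression
#'
#' Probable depression is defined as a total score at or above the cutoff:
#' 8 is the primary screening threshold in older adults, 10 the stricter
#' alternative used in sensitivity analyses.
#'
#' @param score Integer CES-D-10 total(s) in `0:30`.
#' @param cutoff Threshold; 8 (default) or 10. Other values are accepted
#'   with a warning.
#' @return Logical: `TRUE` where `score >= cutoff`.
#' @examples
#' classify_depression(c(7, 8, 10), cutoff = 8)
#' @export
classify_depression <- function(score, cutoff = 8L) {
  if (any(!is.na(score) & (score < 0 | score > 30))) {
    stop("CES-D-10 scores must lie in 0..30")
  }
  if (length(cutoff) != 1L || is.na(cutoff)) stop("cutoff must be a single value")
  if (!cutoff %in% c(8L, 10L)) {
    warning("non-standard CES-D-10 cutoff ", cutoff, " (usual values are 8 and 10)")
  }
  score >= cutoff
}

#' Classify alcohol consumption into four categories
#'
#' Applies the guideline-based partition of drinking behaviour used
#' throughout the package:
#' \describe{
#'   \item{abstainer}{no alcohol consumption at all;}
#'   \item{occasional}{drinking on fewer than one day per week, with no
#'     heavy episodic drinking;}
#'   \item{moderate}{drinking on at least one day per week, with at most 7
#'     (female) or 14 (male) standard drinks per week and no heavy episodic
#'     drinking;}
#'   \item{above_guideline}{weekly volume above the sex-specific limit at a
#'     frequency of at least one day per week, and/or any heavy episodic
#'     drinking with non-zero consumption.}
#' }
#' Weekly drinks are `days_per_week * drinks_per_day` unless supplied
#' directly via `weekly_drinks`. A volume exactly at the sex-specific limit
#' counts as moderate, so the four categories partition the input space.
#' Heavy episodic drinking means five or more standard drinks on one
#' occasion for men, four or more for women, and is taken as a reported
#' flag rather than re-derived.
#'
#' Records with inconsistent zero patterns (drinking days but no drinks,
#' drinks but no drinking days, or heavy episodic drinking with zero
#' consumption) are rejected rather than guessed.
#'
#' @param days_per_week Drinking frequency, days per week, in `[0, 7]`.
#' @param drinks_per_day Average standard drinks per drinking day, `>= 0`.
#' @param heavy_episodic Logical flag for any heavy episodic drinking.
#' @param sex `"male"`/`"female"` (or a factor with those levels).
#' @param weekly_drinks Optional directly reported weekly volume; overrides
#'   the `days * drinks` product.
#' @param female_limit,male_limit Sex-specific weekly-drink limits
#'   (defaults 7 and 14).
#' @return Factor with levels [alcohol_levels]; `NA` inputs give `NA`.
#' @examples
#' classify_alcohol(2, 1, FALSE, "female")   # moderate
#' classify_alcohol(3, 3, FALSE, "female")   # above_guideline (9 > 7/week)
#' @export
classify_alcohol <- function(days_per_week, drinks_per_day, heavy_episodic,
                             sex, weekly_drinks = NULL,
                             female_limit = 7, male_limit = 14) {
  n <- max(length(days_per_week), length(drinks_per_day),
           length(heavy_episodic), length(sex))
  days <- rep_len(as.numeric(days_per_week), n)
  drinks <- rep_len(as.numeric(drinks_per_day), n)
  heavy <- rep_len(as.logical(heavy_episodic), n)
  sex <- rep_len(as.character(sex), n)
  if (!all(is.na(sex) | sex %in% c("male", "female"))) {
    stop("sex must be coded 'male' or 'female'")
  }
  if (any(days < 0 | days > 7, na.rm = TRUE)) {
    stop("days_per_week must lie in [0, 7]; offending rows: ",
         paste(utils::head(which(days < 0 | days > 7)), collapse = ", "))
  }
  if (any(drinks < 0, na.rm = TRUE)) {
    stop("drinks_per_day must be non-negative; offending rows: ",
         paste(utils::head(which(drinks < 0)), collapse = ", "))
  }
  inconsistent <- (days == 0 & drinks > 0) | (days > 0 & drinks == 0) |
    (heavy & days == 0 & drinks == 0)
  if (any(inconsistent, na.rm = TRUE)) {
    stop("inconsistent consumption fields (zero frequency with non-zero ",
         "volume or vice versa, or heavy episodic drinking without ",
         "consumption) at rows: ",
         paste(utils::head(which(inconsistent)), collapse = ", "))
  }
  weekly <- if (is.null(weekly_drinks)) days * drinks else rep_len(as.numeric(weekly_drinks), n)
  limit <- ifelse(sex == "female", female_limit, male_limit)

  out <- rep(NA_character_, n)
  consuming <- days > 0 | drinks > 0
  out[days == 0 & drinks == 0 & !heavy] <- "abstainer"
  out[consuming & days < 1 & !heavy] <- "occasional"
  out[days >= 1 & weekly <= limit & !heavy] <- "moderate"
  out[(days >= 1 & weekly > limit) | (heavy & consuming)] <- "above_guideline"
  factor(out, levels = alcohol_levels)
}
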