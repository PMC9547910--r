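#' Graded Chronic Pain Scale scoring
#'
#' The GCPS (von Korff) grades chronic pain severity from seven self-report
#' items: three pain-intensity ratings (0-10), three interference ratings
#' (0-10) and the number of disability days in the last six months (0-180).
#' The characteristic pain-intensity score is the mean of the three intensity
#' items multiplied by ten (0-100); the disability score is computed the same
#' way from the interference items. Disability days and disability score are
#' each categorised into 0-3 points and summed to 0-6 disability points.
#' Grades: I low disability / low intensity, II low disability / high
#' intensity, III high disability moderately limiting (3-4 points), IV high
#' disability severely limiting (5-6 points).
#'
#' Scores are kept unrounded before thresholding, and every threshold is
#' inclusive at the upper category (intensity exactly 50 is grade II,
#' disability score exactly 70 gives 3 score points).
#'
#' @name gcps
NULL

check_items <- function(..., lo = 0, hi = 10, what = "item") {
  vals <- list(...)
  for (v in vals) {
    if (any(is.na(v) | v < lo | v > hi)) {
      abort(paste0("GCPS ", what, " out of range [", lo, ", ", hi,
                   "] or missing (no missing-item imputation is performed)"))
    }
  }
  invisible(TRUE)
}

#' Characteristic pain-intensity score
#'
#' Mean of the three 0-10 pain items times ten; unrounded, 0-100.
#'
#' @param pain_now,pain_avg,pain_worst Integer vectors in 0-10.
#' @return Numeric vector in \[0, 100\].
#' @export
#' @examples
#' gcps_intensity_score(3, 5, 7) # 50
gcps_intensity_score <- function(pain_now, pain_avg, pain_worst) {
  check_items(pain_now, pain_avg, pain_worst, what = "pain item")
  (pain_now + pain_avg + pain_worst) / 3 * 10
}

#' Disability score
#'
#' Mean of the three 0-10 interference items (daily, social, work
#' activities) times ten; unrounded, 0-100.
#'
#' @param interf_daily,interf_social,interf_work Integer vectors in 0-10.
#' @return Numeric vector in \[0, 100\].
#' @export
gcps_disability_score <- function(interf_daily, interf_social, interf_work) {
  check_items(interf_daily, interf_social, interf_work,
              what = "interference item")
  (interf_daily + interf_social + interf_work) / 3 * 10
}

#' Disability-days points
#'
#' Bins disability days into 0-3 points: 0-6 days -> 0, 7-14 -> 1,
#' 15-30 -> 2, 31-180 -> 3.
#'
#' @param disability_days Integer vector in 0-180.
#' @return Integer vector in 0-3.
#' @export
gcps_days_points <- function(disability_days) {
  check_items(disability_days, lo = 0, hi = 180, what = "disability days")
  ifelse(disability_days >= 31L, 3L,
         ifelse(disability_days >= 15L, 2L,
                ifelse(disability_days >= 7L, 1L, 0L)))
}

#' Disability-score points
#'
#' Bins the 0-100 disability score into 0-3 points at the von Korff
#' cutpoints: 0-29 -> 0, 30-49 -> 1, 50-69 -> 2, 70+ -> 3.
#'
#' @param disability_score Numeric vector in 0-100.
#' @return Integer vector in 0-3.
#' @export
gcps_score_points <- function(disability_score) {
  check_items(disability_score, lo = 0, hi = 100, what = "disability score")
  ifelse(disability_score >= 70, 3L,
         ifelse(disability_score >= 50, 2L,
                ifelse(disability_score >= 30, 1L, 0L)))
}

gcps_grade_levels <- c("I", "II", "III", "IV")

#' Assign the GCPS grade
#'
#' Grades I/II are separated by pain intensity (< 50 vs >= 50) when the
#' disability points are 0-2; 3-4 points give grade III and 5-6 points
#' grade IV regardless of intensity (disability dominates intensity).
#'
#' @param pain_intensity Numeric vector in 0-100.
#' @param disability_points Integer vector in 0-6.
#' @return Ordered factor with levels `I < II < III < IV`.
#' @export
#' @examples
#' gcps_grade(40, 2) # I
#' gcps_grade(20, 5) # IV
gcps_grade <- function(pain_intensity, disability_points) {
  if (any(is.na(disability_points) | disability_points < 0L |
            disability_points > 6L)) {
    abort("disability_points must be integers in 0-6")
  }
  check_items(pain_intensity, lo = 0, hi = 100, what = "pain intensity")
  g <- ifelse(disability_points >= 5L, 4L,
              ifelse(disability_points >= 3L, 3L,
                     ifelse(pain_intensity >= 50, 2L, 1L)))
  factor(gcps_grade_levels[g], levels = gcps_grade_levels, ordered = TRUE)
}

#' Collapse the four GCPS grades to three levels
#'
#' For comparison with the three-level chronicity class, grades I and II
#' are combined into level 1; grade III becomes level 2 and grade IV
#' level 3.
#'
#' @param grade Factor/character vector with values I, II, III, IV.
#' @return Ordered factor with levels `1 < 2 < 3`.
#' @export
gcps_collapse3 <- function(grade) {
  g <- as.character(grade)
  bad <- !(g %in% gcps_grade_levels)
  if (any(bad)) abort("grade must be one of I, II, III, IV")
  lev3 <- c(I = "1", II = "1", III = "2", IV = "3")[g]
  factor(lev3, levels = c("1", "2", "3"), ordered = TRUE)
}

#' Dichotomise the GCPS grade into severe / non-severe
#'
#' Grades III and IV (high disability) are labelled severe; grades I and II
#' non-severe. Equivalent to `disability_points >= 3`.
#'
#' @inheritParams gcps_collapse3
#' @return Logical vector, `TRUE` for severe.
#' @export
gcps_severe <- function(grade) {
  gcps_collapse3(grade) %in% c("2", "3")
}

#' Score a table of GCPS questionnaire responses
#'
#' Applies the full scoring chain to a `gcps_items` table (see
#' [read_claims_tables()]). All seven items must be present and in range:
#' the digital assessment that produced such data was mandatory, so a
#' missing item is a hard validation error rather than something to impute.
#' An all-zero response (no pain, no disability) still receives grade I,
#' with a warning, so the codomain stays at the instrument's four grades.
#'
#' @param items Tibble with columns `person_id`, `pain_now`, `pain_avg`,
#'   `pain_worst`, `interf_daily`, `interf_social`, `interf_work`,
#'   `disability_days`.
#' @return Tibble with one row per person: `person_id`, `pain_intensity`,
#'   `disability_score`, `days_points`, `score_points`, `disability_points`,
#'   `grade`, `grade3`, `severe`.
#' @export
score_gcps <- function(items) {
  needed <- names(claims_schemas()$gcps_items$cols)
  missing_cols <- setdiff(needed, names(items))
  if (length(missing_cols) > 0) {
    abort(paste0("gcps_items is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  pi <- gcps_intensity_score(items$pain_now, items$pain_avg, items$pain_worst)
  ds <- gcps_disability_score(items$interf_daily, items$interf_social,
                              items$interf_work)
  dp_days <- gcps_days_points(items$disability_days)
  dp_score <- gcps_score_points(ds)
  points <- dp_days + dp_score
  grade <- gcps_grade(pi, points)
  pain_free <- pi == 0 & points == 0L
  if (any(pain_free)) {
    warn(paste0(sum(pain_free), " response(s) report no pain and no ",
                "disability; graded I (the scale has no pain-free grade)"))
  }
  tibble(
    person_id = items$person_id,
    pain_intensity = pi,
    disability_score = ds,
    days_points = dp_days,
    score_points = dp_score,
    disability_points = points,
    grade = grade,
    grade3 = gcps_collapse3(grade),
    severe = gcps_severe(grade)
  )
}
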