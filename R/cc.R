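#' Configuration of the claims-based chronicity classifier
#'
#' Holds the code lists and thresholds of the three-class back-pain
#' chronicity rules applied to a 12-month claims lookback window:
#' the ICD-10 dorsopathy range M40-M54, the psychiatric F-diagnosis risk
#' list, the strong-opioid ATC prefix N02A, the six-month (183-day) opioid
#' pair window, and the six-week (42-day) sick-leave threshold.
#'
#' F-codes given as a three- or four-character stem with `*` (and the
#' stem-only entries F38 and F54) match any child code by prefix; fully
#' specified codes such as `F43.21` match exactly.
#'
#' @param lookback_days Length of the closed lookback window in days.
#' @param bp_code_range Character vector of length 2: the inclusive ICD-10
#'   three-character root range of back-pain diagnoses.
#' @param f_code_list Character vector of F-diagnosis patterns.
#' @param opioid_atc_prefix ATC prefix identifying strong opioids.
#' @param opioid_window_days Maximum gap in days between two opioid
#'   prescriptions for them to count as a pair "within six months".
#' @param sickleave_chronic_days Back-pain sick-leave days at or above which
#'   the class is 3 ("at least six weeks").
#' @param dedupe_diagnoses If `TRUE`, diagnosis records that repeat the same
#'   `(person_id, code, date)` are counted once. Off by default: the rules
#'   count diagnosis records, and claims data legitimately repeat codes.
#' @return A list of class `cc_config`.
#' @export
cc_config <- function(lookback_days = 365L,
                      bp_code_range = c("M40", "M54"),
                      f_code_list = c("F32*", "F33*", "F34.1", "F34.8",
                                      "F34.9", "F38*", "F41.2", "F45.4",
                                      "F48.0", "F43.20", "F43.21", "F43.22",
                                      "F54*", "F62.80"),
                      opioid_atc_prefix = "N02A",
                      opioid_window_days = 183L,
                      sickleave_chronic_days = 42L,
                      dedupe_diagnoses = FALSE) {
  stopifnot(lookback_days > 0, opioid_window_days > 0,
            sickleave_chronic_days > 0, length(bp_code_range) == 2)
  if (!all(grepl("^[A-Z][0-9]{2}$", bp_code_range))) {
    abort("bp_code_range must be two 3-character ICD-10 roots, e.g. c('M40','M54')")
  }
  if (!all(grepl("^[A-Z][0-9]{2}(\\.[0-9]{1,2})?\\*?$", f_code_list))) {
    abort("f_code_list entries must be ICD-10 codes, optionally ending in '*'")
  }
  structure(
    list(lookback_days = as.integer(lookback_days),
         bp_code_range = bp_code_range,
         f_code_list = f_code_list,
         opioid_atc_prefix = opioid_atc_prefix,
         opioid_window_days = as.integer(opioid_window_days),
         sickleave_chronic_days = as.integer(sickleave_chronic_days),
         dedupe_diagnoses = isTRUE(dedupe_diagnoses)),
    class = "cc_config"
  )
}

# M40-M54 membership: the 3-character root is compared lexically, so any
# 4th/5th digit variant of a root inside the range matches.
icd_in_bp_range <- function(code, range = c("M40", "M54")) {
  root <- substr(code, 1, 3)
  !is.na(code) & root >= range[1] & root <= range[2]
}

# F-list membership: starred / stem-only patterns match by prefix,
# fully specified codes match exactly.
icd_matches_f_list <- function(code, patterns) {
  starred <- grepl("\\*$", patterns)
  prefixes <- sub("\\*$", "", patterns[starred])
  exact <- patterns[!starred]
  hit <- code %in% exact
  for (p in prefixes) {
    hit <- hit | startsWith(code, p)
  }
  hit & !is.na(code)
}

# Days of overlap between closed episode [start, end] and closed window.
episode_overlap_days <- function(start, end, window) {
  lo <- pmax(start, window$start)
  hi <- pmin(end, window$end)
  pmax(as.integer(hi - lo) + 1L, 0L)
}

#' Extract the chronicity-rule feature summary for one person
#'
#' Counts, over the closed lookback window ending at `index_date`
#' (the invitation date in the validation study): back-pain M40-M54
#' diagnosis records, F-diagnosis records from the risk list, opioid
#' (N02A) prescriptions and whether any two of them fall within the
#' six-month pair window, and the cumulative back-pain-attributed
#' sick-leave days clipped to the window.
#'
#' @param history Named list with tibbles `diagnoses`, `prescriptions`,
#'   `sick_leave` (any may be absent or empty).
#' @param index_date `Date` scalar anchoring the lookback window.
#' @param config A [cc_config()].
#' @return One-row tibble: `m_diag_count`, `f_diag_count`,
#'   `opioid_rx_count`, `opioid_rx_pair_within_window`, `bp_sickleave_days`.
#' @export
cc_extract_features <- function(history, index_date, config = cc_config()) {
  stopifnot(inherits(index_date, "Date"), length(index_date) == 1)
  win <- lookback_window(index_date, config$lookback_days)

  dg <- history$diagnoses
  if (is.null(dg)) dg <- tibble(code = character(), date = as.Date(character()))
  dg <- dg[in_window(dg$date, win), , drop = FALSE]
  if (config$dedupe_diagnoses) {
    dg <- dplyr::distinct(dg, .data$code, .data$date, .keep_all = TRUE)
  }
  m_count <- sum(icd_in_bp_range(dg$code, config$bp_code_range))
  f_count <- sum(icd_matches_f_list(dg$code, config$f_code_list))

  rx <- history$prescriptions
  if (is.null(rx)) rx <- tibble(atc_code = character(), date = as.Date(character()))
  rx <- rx[in_window(rx$date, win) &
             startsWith(rx$atc_code, config$opioid_atc_prefix), , drop = FALSE]
  n_rx <- nrow(rx)
  pair <- opioid_pair_within(rx$date, config$opioid_window_days)

  sl <- history$sick_leave
  if (is.null(sl)) {
    sl <- tibble(start = as.Date(character()), end = as.Date(character()),
                 attributed_code = character())
  }
  sl <- sl[icd_in_bp_range(sl$attributed_code, config$bp_code_range), , drop = FALSE]
  sl_days <- sum(episode_overlap_days(sl$start, sl$end, win))

  tibble(m_diag_count = m_count, f_diag_count = f_count,
         opioid_rx_count = n_rx,
         opioid_rx_pair_within_window = pair,
         bp_sickleave_days = as.integer(sl_days))
}

# Two dates at most `gap` days apart exist iff the minimum gap between
# consecutive sorted dates is <= gap.
opioid_pair_within <- function(dates, gap) {
  if (length(dates) < 2) return(FALSE)
  d <- sort(dates)
  min(as.integer(diff(d))) <= gap
}

cc_levels <- c("1", "2", "3", "not_classifiable")

#' Assign the chronicity class from rule features
#'
#' Persons with fewer than two back-pain diagnosis records in the window do
#' not meet the minimum requirement and are `not_classifiable`. Otherwise,
#' with precedence 3 > 2 > 1:
#' class 3 (evidence of chronicity) when back-pain sick leave reaches six
#' weeks or an opioid prescription pair falls within six months; class 2
#' (evidence of risk) when there is some but less than six weeks of
#' back-pain sick leave, or at least two F diagnoses; class 1 otherwise.
#'
#' @param features Tibble as returned by [cc_extract_features()]
#'   (one or more rows).
#' @param config A [cc_config()] supplying the thresholds.
#' @return Factor vector with levels `1`, `2`, `3`, `not_classifiable`.
#' @export
cc_classify <- function(features, config = cc_config()) {
  f <- features
  with(f, {
    if (any(m_diag_count < 0 | f_diag_count < 0 | opioid_rx_count < 0 |
              bp_sickleave_days < 0)) {
      abort("feature counts must be non-negative")
    }
    if (any(opioid_rx_pair_within_window & opioid_rx_count < 2)) {
      abort("opioid pair flagged with fewer than two prescriptions")
    }
  })
  cc3 <- f$bp_sickleave_days >= config$sickleave_chronic_days |
    f$opioid_rx_pair_within_window
  cc2 <- (f$bp_sickleave_days >= 1L &
            f$bp_sickleave_days < config$sickleave_chronic_days) |
    f$f_diag_count >= 2L
  out <- ifelse(f$m_diag_count < 2L, "not_classifiable",
                ifelse(cc3, "3", ifelse(cc2, "2", "1")))
  factor(out, levels = cc_levels)
}

#' Dichotomise the chronicity class into severe / non-severe
#'
#' Classes 1 and 2 are non-severe, class 3 severe. `not_classifiable`
#' values are a domain error: they must be filtered out upstream.
#'
#' @param cc Factor/character vector of chronicity classes.
#' @return Logical vector, `TRUE` for severe.
#' @export
cc_severe <- function(cc) {
  ccc <- as.character(cc)
  if (any(!(ccc %in% c("1", "2", "3")))) {
    abort("cc must be 1, 2 or 3 (not_classifiable persons cannot be dichotomised)")
  }
  ccc == "3"
}

#' Classify every person in a claims bundle
#'
#' Vectorised front end to [cc_extract_features()] + [cc_classify()]:
#' computes the rule features for every person in one pass over the claims
#' tables, anchored per person at `index_date` (by default the invitation
#' date from the enrolment table; self-selected persons, who have no
#' invitation, are anchored at their enrolment date).
#'
#' @param data Named list with tibbles `diagnoses`, `prescriptions`,
#'   `sick_leave` and `enrolment`.
#' @param config A [cc_config()].
#' @param index_dates Optional tibble `person_id`, `index_date` overriding
#'   the default anchoring.
#' @return Tibble with one row per person in the enrolment table:
#'   `person_id`, the five feature columns, `cc` and `severe`
#'   (`NA` for not-classifiable persons).
#' @export
classify_cc <- function(data, config = cc_config(), index_dates = NULL) {
  enr <- data$enrolment
  if (is.null(enr)) abort("data must contain an enrolment table")
  if (is.null(index_dates)) {
    index_dates <- tibble(
      person_id = enr$person_id,
      index_date = dplyr::coalesce(enr$invitation_date, enr$enrolment_date)
    )
  }
  idx <- index_dates
  win_start <- idx$index_date - config$lookback_days + 1L

  join_window <- function(df, date_col) {
    df <- dplyr::inner_join(df, idx, by = "person_id")
    df[df[[date_col]] >= (df$index_date - config$lookback_days + 1L) &
         df[[date_col]] <= df$index_date, , drop = FALSE]
  }

  dg <- data$diagnoses %||%
    tibble(person_id = character(), code = character(),
           date = as.Date(character()))
  dg <- join_window(dg, "date")
  if (config$dedupe_diagnoses) {
    dg <- dplyr::distinct(dg, .data$person_id, .data$code, .data$date,
                          .keep_all = TRUE)
  }
  diag_feats <- dg |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(
      m_diag_count = sum(icd_in_bp_range(.data$code, config$bp_code_range)),
      f_diag_count = sum(icd_matches_f_list(.data$code, config$f_code_list)),
      .groups = "drop"
    )

  rx <- data$prescriptions %||%
    tibble(person_id = character(), atc_code = character(),
           date = as.Date(character()))
  rx <- join_window(rx[startsWith(rx$atc_code, config$opioid_atc_prefix), ,
                       drop = FALSE], "date")
  rx_feats <- rx |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(
      opioid_rx_count = dplyr::n(),
      opioid_rx_pair_within_window =
        opioid_pair_within(.data$date, config$opioid_window_days),
      .groups = "drop"
    )

  sl <- data$sick_leave %||%
    tibble(person_id = character(), start = as.Date(character()),
           end = as.Date(character()), attributed_code = character())
  sl <- sl[icd_in_bp_range(sl$attributed_code, config$bp_code_range), ,
           drop = FALSE]
  sl <- dplyr::inner_join(sl, idx, by = "person_id")
  sl$overlap <- episode_overlap_days(
    sl$start, sl$end,
    list(start = sl$index_date - config$lookback_days + 1L,
         end = sl$index_date)
  )
  sl_feats <- sl |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(bp_sickleave_days = as.integer(sum(.data$overlap)),
                     .groups = "drop")

  feats <- tibble(person_id = idx$person_id) |>
    dplyr::left_join(diag_feats, by = "person_id") |>
    dplyr::left_join(rx_feats, by = "person_id") |>
    dplyr::left_join(sl_feats, by = "person_id") |>
    tidyr::replace_na(list(m_diag_count = 0L, f_diag_count = 0L,
                           opioid_rx_count = 0L,
                           opioid_rx_pair_within_window = FALSE,
                           bp_sickleave_days = 0L))
  feats$cc <- cc_classify(feats, config)
  feats$severe <- ifelse(feats$cc == "not_classifiable", NA,
                         feats$cc == "3")
  feats
}
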