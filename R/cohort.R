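#' Flag invoice availability in the year before enrolment
#'
#' Persons with a deductible tariff often submit no invoices at all; such
#' persons carry no usable cost information and are excluded from every
#' analysis cohort. The flag is `TRUE` when at least one invoice falls in
#' the closed 365-day window ending at the enrolment date (note the anchor:
#' enrolment date here, invitation date for the chronicity lookback).
#'
#' @param invoices Tibble with `person_id`, `date`.
#' @param enrolment Tibble with `person_id`, `enrolment_date`.
#' @param window_days Window length in days.
#' @return Tibble `person_id`, `has_any_invoice_12mo`.
#' @export
flag_invoice_availability <- function(invoices, enrolment,
                                      window_days = 365L) {
  inv <- invoices %||% tibble(person_id = character(),
                              date = as.Date(character()))
  joined <- dplyr::inner_join(
    inv[, c("person_id", "date")],
    enrolment[, c("person_id", "enrolment_date")],
    by = "person_id"
  )
  hit <- joined[joined$date >= (joined$enrolment_date - window_days + 1L) &
                  joined$date <= joined$enrolment_date, , drop = FALSE]
  tibble(person_id = enrolment$person_id,
         has_any_invoice_12mo = enrolment$person_id %in% hit$person_id)
}

#' Flag enrolment within the post-invitation window
#'
#' The chronicity class is only known at the invitation date, so persons
#' who took more than `max_days` (default 90) days from invitation to
#' enrolment are excluded from the validation cohort; "within 90 days" is
#' inclusive. Self-selected persons have no invitation and are never
#' flagged.
#'
#' @param enrolment Tibble with `person_id`, `invitation_date`,
#'   `enrolment_date`, `path`.
#' @param max_days Maximum allowed invitation-to-enrolment gap in days.
#' @return Tibble `person_id`, `invited`, `enrolled_within_90d`.
#' @export
flag_enrolment_window <- function(enrolment, max_days = 90L) {
  invited <- enrolment$path == "invited"
  gap <- as.integer(enrolment$enrolment_date - enrolment$invitation_date)
  tibble(person_id = enrolment$person_id,
         invited = invited,
         enrolled_within_90d = invited & !is.na(gap) & gap <= max_days)
}

#' Build the analysis cohorts and the selection-cascade ledger
#'
#' Combines the availability and enrolment-window flags into the three
#' nested analysis cohorts: the cost cohort (any invoice available), the
#' validation cohort (additionally invited and enrolled within the window)
#' and the sick-leave-insured subgroup used for the sensitivity analysis.
#'
#' @param enrolment Tibble with `person_id`, `invitation_date`,
#'   `enrolment_date`, `path`, `sick_leave_insured`.
#' @param invoices Tibble with `person_id`, `date` (may be empty).
#' @param window_days Invoice-availability window in days.
#' @param max_enrol_days Maximum invitation-to-enrolment gap in days.
#' @return A list with `flags` (one row per person), `cohorts` (named list
#'   of person-id vectors: `cost_cohort`, `validation_cohort`,
#'   `sickleave_subgroup`) and `ledger`, a tibble of cascade counts
#'   (step, n) mirroring the data-preparation table of the study design.
#' @export
select_cohorts <- function(enrolment, invoices,
                           window_days = 365L, max_enrol_days = 90L) {
  if (is.null(invoices)) {
    # no invoice table at all: the availability exclusion is inapplicable
    # (as opposed to a person with zero invoices, who is excluded)
    warn("no invoices table supplied; skipping the invoice-availability exclusion")
    fi <- tibble(person_id = enrolment$person_id,
                 has_any_invoice_12mo = TRUE)
  } else {
    fi <- flag_invoice_availability(invoices, enrolment, window_days)
  }
  fe <- flag_enrolment_window(enrolment, max_enrol_days)
  flags <- dplyr::left_join(fi, fe, by = "person_id")
  flags$sick_leave_insured <- enrolment$sick_leave_insured[
    match(flags$person_id, enrolment$person_id)]

  cost <- flags$person_id[flags$has_any_invoice_12mo]
  valid <- flags$person_id[flags$has_any_invoice_12mo & flags$invited &
                             flags$enrolled_within_90d]
  sub <- flags$person_id[flags$has_any_invoice_12mo & flags$invited &
                           flags$enrolled_within_90d &
                           flags$sick_leave_insured]
  ledger <- tibble(
    step = c("study_size",
             "with_billing_invoice_available",
             "enrolment_after_invitation",
             "enrolment_within_90_days",
             "plus_insured_against_sick_leave"),
    n = c(nrow(flags), length(cost),
          sum(flags$has_any_invoice_12mo & flags$invited),
          length(valid), length(sub))
  )
  list(flags = flags,
       cohorts = list(cost_cohort = cost,
                      validation_cohort = valid,
                      sickleave_subgroup = sub),
       ledger = ledger)
}
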