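# Small in-code fixtures shared across test files.

empty_history <- function() {
  list(
    diagnoses = tibble::tibble(person_id = character(), code = character(),
                               date = as.Date(character())),
    prescriptions = tibble::tibble(person_id = character(),
                                   atc_code = character(),
                                   date = as.Date(character())),
    sick_leave = tibble::tibble(person_id = character(),
                                start = as.Date(character()),
                                end = as.Date(character()),
                                attributed_code = character())
  )
}

# A three-person bundle with hand-written records covering all six tables.
tiny_bundle <- function() {
  d0 <- as.Date("2020-06-01")
  list(
    diagnoses = tibble::tibble(
      person_id = c("A", "A", "B", "C"),
      code = c("M54.5", "M54.5", "M51.2", "F43.21"),
      date = d0 - c(10, 40, 100, 5)
    ),
    prescriptions = tibble::tibble(
      person_id = c("A", "B"),
      atc_code = c("N02AA05", "M01AE01"),
      date = d0 - c(30, 60)
    ),
    sick_leave = tibble::tibble(
      person_id = "B",
      start = d0 - 80, end = d0 - 61,
      attributed_code = "M54.4"
    ),
    invoices = tibble::tibble(
      person_id = c("A", "B", "B"),
      date = d0 - c(100, 20, 300),
      category = c("total_health", "bp_outpatient", "total_health"),
      amount = c(1200.50, 80, 340.25),
      year = c(2020L, 2020L, 2019L)
    ),
    enrolment = tibble::tibble(
      person_id = c("A", "B", "C"),
      invitation_date = c(d0 - 30, d0 - 5, as.Date(NA)),
      enrolment_date = c(d0, d0, d0),
      path = c("invited", "invited", "self_selected"),
      sick_leave_insured = c(TRUE, FALSE, TRUE)
    ),
    gcps_items = tibble::tibble(
      person_id = c("A", "B", "C"),
      pain_now = c(2L, 6L, 8L), pain_avg = c(3L, 7L, 9L),
      pain_worst = c(4L, 8L, 10L),
      interf_daily = c(1L, 5L, 9L), interf_social = c(0L, 6L, 8L),
      interf_work = c(2L, 7L, 10L),
      disability_days = c(3L, 20L, 90L)
    )
  )
}

# Sort a table by all columns, for order-insensitive comparison.
sort_all <- function(df) {
  df[do.call(order, as.list(df)), , drop = FALSE]
}

expect_same_content <- function(a, b) {
  expect_equal(as.data.frame(sort_all(a)), as.data.frame(sort_all(b)),
               ignore_attr = TRUE)
}
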