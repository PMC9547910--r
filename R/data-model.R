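#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

# Column schemas for the six interchange tables. One file per record type,
# CSV/UTF-8, ISO-8601 dates, "." decimal separator (locale-independent).
claims_schemas <- function() {
  list(
    diagnoses = readr::cols(
      person_id = readr::col_character(),
      code = readr::col_character(),
      date = readr::col_date(format = "%Y-%m-%d")
    ),
    prescriptions = readr::cols(
      person_id = readr::col_character(),
      atc_code = readr::col_character(),
      date = readr::col_date(format = "%Y-%m-%d")
    ),
    sick_leave = readr::cols(
      person_id = readr::col_character(),
      start = readr::col_date(format = "%Y-%m-%d"),
      end = readr::col_date(format = "%Y-%m-%d"),
      attributed_code = readr::col_character()
    ),
    invoices = readr::cols(
      person_id = readr::col_character(),
      date = readr::col_date(format = "%Y-%m-%d"),
      category = readr::col_character(),
      amount = readr::col_double(),
      year = readr::col_integer()
    ),
    enrolment = readr::cols(
      person_id = readr::col_character(),
      invitation_date = readr::col_date(format = "%Y-%m-%d"),
      enrolment_date = readr::col_date(format = "%Y-%m-%d"),
      path = readr::col_character(),
      sick_leave_insured = readr::col_logical()
    ),
    gcps_items = readr::cols(
      person_id = readr::col_character(),
      pain_now = readr::col_integer(),
      pain_avg = readr::col_integer(),
      pain_worst = readr::col_integer(),
      interf_daily = readr::col_integer(),
      interf_social = readr::col_integer(),
      interf_work = readr::col_integer(),
      disability_days = readr::col_integer()
    )
  )
}

#' Test strings for ICD-10 code syntax
#'
#' A syntactically valid code is a letter, two digits and an optional
#' sub-code of one or two digits after a dot, e.g. `"M54.5"` or `"F62.80"`.
#'
#' @param code Character vector of candidate codes.
#' @return Logical vector.
#' @export
#' @examples
#' is_icd10(c("M54.5", "F43.21", "M545", "x10"))
is_icd10 <- function(code) {
  grepl("^[A-Z][0-9]{2}(\\.[0-9]{1,2})?$", code)
}

# Invoice categories stored on disk; bp_total is always derived, never stored.
invoice_categories <- c("total_health", "bp_inpatient", "bp_outpatient")

# Per-table row validation. Returns a tibble of problems
# (table, row, column, message); zero rows means the table is valid.
validate_table <- function(name, df) {
  probs <- list()
  note <- function(rows, column, message) {
    if (length(rows) > 0) {
      probs[[length(probs) + 1L]] <<-
        tibble(table = name, row = rows, column = column, message = message)
    }
  }
  bad_date <- function(col) which(is.na(df[[col]]))
  switch(name,
    diagnoses = {
      note(which(!is_icd10(df$code)), "code", "not a valid ICD-10 code")
      note(bad_date("date"), "date", "missing or malformed date")
    },
    prescriptions = {
      note(which(is.na(df$atc_code) | !grepl("^[A-Z0-9]+$", df$atc_code)),
           "atc_code", "ATC code must be non-empty uppercase alphanumeric")
      note(bad_date("date"), "date", "missing or malformed date")
    },
    sick_leave = {
      note(which(!is_icd10(df$attributed_code)), "attributed_code",
           "not a valid ICD-10 code")
      note(bad_date("start"), "start", "missing or malformed date")
      note(bad_date("end"), "end", "missing or malformed date")
      note(which(!is.na(df$start) & !is.na(df$end) & df$end < df$start),
           "end", "episode end before start")
    },
    invoices = {
      note(which(is.na(df$amount) | df$amount < 0), "amount",
           "amount must be a non-negative number")
      note(which(!(df$category %in% invoice_categories)), "category",
           paste0("category must be one of ",
                  paste(invoice_categories, collapse = ", ")))
      note(bad_date("date"), "date", "missing or malformed date")
      note(which(is.na(df$year)), "year", "missing year")
    },
    enrolment = {
      note(bad_date("enrolment_date"), "enrolment_date",
           "missing or malformed date")
      note(which(!(df$path %in% c("invited", "self_selected"))), "path",
           "path must be 'invited' or 'self_selected'")
      inv <- df$path == "invited"
      note(which(inv & is.na(df$invitation_date)), "invitation_date",
           "invited persons must have an invitation date")
      note(which(inv & !is.na(df$invitation_date) &
                   df$invitation_date > df$enrolment_date),
           "invitation_date", "invitation date after enrolment date")
      note(which(is.na(df$sick_leave_insured)), "sick_leave_insured",
           "missing sick-leave insurance flag")
    },
    gcps_items = {
      for (col in c("pain_now", "pain_avg", "pain_worst",
                    "interf_daily", "interf_social", "interf_work")) {
        note(which(is.na(df[[col]]) | df[[col]] < 0L | df[[col]] > 10L),
             col, "item must be an integer in 0-10")
      }
      note(which(is.na(df$disability_days) | df$disability_days < 0L |
                   df$disability_days > 180L),
           "disability_days", "disability days must be in 0-180")
    }
  )
  if (length(probs) == 0) {
    tibble(table = character(), row = integer(),
           column = character(), message = character())
  } else {
    dplyr::arrange(dplyr::bind_rows(probs), .data$row)
  }
}

#' Validate a claims/questionnaire data bundle
#'
#' Checks each table of a bundle (as returned by [read_claims_tables()] or
#' [generate_population()]) against its record-type invariants: ICD-10 and
#' ATC code syntax, date validity, episode ordering, amount sign, invoice
#' category membership, enrolment-path consistency and GCPS item ranges.
#'
#' @param data Named list of tibbles (any subset of `diagnoses`,
#'   `prescriptions`, `sick_leave`, `invoices`, `enrolment`, `gcps_items`).
#' @return A tibble of problems with columns `table`, `row`, `column`,
#'   `message`; zero rows when the bundle is valid.
#' @export
validate_claims_tables <- function(data) {
  known <- intersect(names(claims_schemas()), names(data))
  dplyr::bind_rows(lapply(known, function(nm) validate_table(nm, data[[nm]])))
}

#' Read the claims + questionnaire CSV bundle
#'
#' Reads the per-record-type CSV files written by [write_claims_tables()]
#' (or prepared to the same schema) and validates every row. Duplicate
#' `(person_id, record)` rows are kept: claims data legitimately repeat the
#' same code on several dates, and the chronicity rules count records.
#'
#' @param dir Directory containing `diagnoses.csv`, `prescriptions.csv`,
#'   `sick_leave.csv`, `invoices.csv`, `enrolment.csv`, `gcps_items.csv`.
#'   Missing files are skipped.
#' @param strict If `TRUE` (default) any invariant-violating row aborts with
#'   a row-numbered error report; if `FALSE` the problem report is attached
#'   as attribute `"problems"` and all rows are returned as read.
#' @return Named list of tibbles, one per file found.
#' @export
read_claims_tables <- function(dir, strict = TRUE) {
  schemas <- claims_schemas()
  out <- list()
  for (nm in names(schemas)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) next
    df <- readr::read_csv(path, col_types = schemas[[nm]],
                          locale = readr::locale(decimal_mark = "."),
                          progress = FALSE)
    out[[nm]] <- as_tibble(df)
  }
  if (length(out) == 0) {
    abort(paste0("no claims tables found under '", dir, "'"))
  }
  problems <- validate_claims_tables(out)
  if (nrow(problems) > 0) {
    if (strict) {
      head_probs <- utils::head(problems, 10)
      abort(c(
        paste0(nrow(problems), " invalid row(s) in claims tables"),
        paste0(head_probs$table, " row ", head_probs$row, " [",
               head_probs$column, "]: ", head_probs$message)
      ))
    }
    attr(out, "problems") <- problems
  }
  out
}

#' Write the claims + questionnaire CSV bundle
#'
#' Writes one CSV per record type with a deterministic column order and row
#' order (sorted by person id, then date/start), so that identical data
#' always produce byte-identical files and
#' `read_claims_tables(write_claims_tables(x))` is the identity.
#'
#' @param data Named list of tibbles as produced by [read_claims_tables()]
#'   or [generate_population()].
#' @param dir Output directory; created if absent.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_claims_tables <- function(data, dir) {
  probs <- validate_claims_tables(data)
  if (nrow(probs) > 0) {
    abort(paste0("refusing to write invalid data: ",
                 nrow(probs), " problem row(s); see validate_claims_tables()"))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  schemas <- claims_schemas()
  sort_keys <- list(
    diagnoses = c("person_id", "date", "code"),
    prescriptions = c("person_id", "date", "atc_code"),
    sick_leave = c("person_id", "start", "end", "attributed_code"),
    invoices = c("person_id", "date", "category", "amount"),
    enrolment = c("person_id"),
    gcps_items = c("person_id")
  )
  paths <- character()
  for (nm in intersect(names(schemas), names(data))) {
    cols <- names(schemas[[nm]]$cols)
    df <- data[[nm]][, cols]
    df <- dplyr::arrange(df, dplyr::across(dplyr::all_of(sort_keys[[nm]])))
    path <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(df, path, progress = FALSE)
    paths[nm] <- path
  }
  invisible(paths)
}

# Closed-interval lookback window of `days` days ending at `index_date`:
# [index_date - days + 1, index_date]. All window logic in the package uses
# this helper so the closure convention lives in exactly one place.
lookback_window <- function(index_date, days) {
  list(start = index_date - days + 1L, end = index_date)
}

in_window <- function(date, window) {
  !is.na(date) & date >= window$start & date <= window$end
}
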