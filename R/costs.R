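#' Default consumer-price-index table (Germany, 2015 = 100)
#'
#' Editable placeholder CPI series for 2013-2021 used to convert nominal
#' invoice amounts to base-year (default 2020) euros. Replace with the
#' official series of the study country when analysing real data.
#'
#' @return Tibble with columns `year`, `cpi`.
#' @export
default_cpi_table <- function() {
  tibble(year = 2013:2021,
         cpi = c(98.9, 99.5, 100.0, 100.5, 102.0, 103.8, 105.3, 105.8, 109.1))
}

#' Convert a nominal amount to base-year euros
#'
#' `amount * cpi[base_year] / cpi[invoice_year]`.
#'
#' @param amount Numeric vector of nominal euro amounts.
#' @param invoice_year Integer vector of invoice years.
#' @param cpi_table Tibble `year`, `cpi` covering both years.
#' @param base_year Target price year.
#' @return Numeric vector in base-year euros.
#' @export
#' @examples
#' cpi_adjust(100, 2015, base_year = 2020) # 105.8
cpi_adjust <- function(amount, invoice_year, cpi_table = default_cpi_table(),
                       base_year = 2020L) {
  if (is.null(cpi_table) || nrow(cpi_table) == 0) {
    abort("cpi_table is empty")
  }
  base_cpi <- cpi_table$cpi[match(base_year, cpi_table$year)]
  year_cpi <- cpi_table$cpi[match(invoice_year, cpi_table$year)]
  if (is.na(base_cpi)) abort(paste0("base year ", base_year, " not in cpi_table"))
  if (any(is.na(year_cpi))) {
    abort(paste0("invoice year(s) missing from cpi_table: ",
                 paste(sort(unique(invoice_year[is.na(year_cpi)])),
                       collapse = ", ")))
  }
  amount * base_cpi / year_cpi
}

cost_categories <- c("total_health", "bp_total", "bp_inpatient", "bp_outpatient")

#' Aggregate per-person 12-month pre-enrolment costs
#'
#' Sums CPI-adjusted invoice amounts per category over the closed 365-day
#' window ending at each person's enrolment date. `bp_total` is derived as
#' inpatient + outpatient. Persons without any invoice in the window get
#' all-zero rows.
#'
#' @param invoices Tibble `person_id`, `date`, `category`, `amount`, `year`.
#' @param enrolment Tibble `person_id`, `enrolment_date`.
#' @param cpi_table,base_year Passed to [cpi_adjust()]; `cpi_table = NULL`
#'   skips price adjustment.
#' @param window_days Aggregation window in days.
#' @return Tibble `person_id`, `total_health`, `bp_total`, `bp_inpatient`,
#'   `bp_outpatient` (euros, base-year prices), plus per-category logical
#'   `low_cost_*` flags (no invoice of that category in the window).
#' @export
aggregate_costs <- function(invoices, enrolment,
                            cpi_table = default_cpi_table(),
                            base_year = 2020L, window_days = 365L) {
  inv <- invoices %||%
    tibble(person_id = character(), date = as.Date(character()),
           category = character(), amount = double(), year = integer())
  joined <- dplyr::inner_join(
    inv, enrolment[, c("person_id", "enrolment_date")], by = "person_id")
  joined <- joined[joined$date >= (joined$enrolment_date - window_days + 1L) &
                     joined$date <= joined$enrolment_date, , drop = FALSE]
  joined$amount_adj <- if (is.null(cpi_table)) joined$amount else
    cpi_adjust(joined$amount, joined$year, cpi_table, base_year)

  sums <- joined |>
    dplyr::group_by(.data$person_id, .data$category) |>
    dplyr::summarise(total = sum(.data$amount_adj), n_inv = dplyr::n(),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "category",
                       values_from = c("total", "n_inv"),
                       values_fill = list(total = 0, n_inv = 0L))
  for (cat in invoice_categories) {
    for (pref in c("total_", "n_inv_")) {
      col <- paste0(pref, cat)
      if (!col %in% names(sums)) sums[[col]] <- if (pref == "total_") 0 else 0L
    }
  }
  out <- tibble(person_id = enrolment$person_id) |>
    dplyr::left_join(sums, by = "person_id") |>
    tidyr::replace_na(list(total_total_health = 0, total_bp_inpatient = 0,
                           total_bp_outpatient = 0, n_inv_total_health = 0L,
                           n_inv_bp_inpatient = 0L, n_inv_bp_outpatient = 0L))
  tibble(
    person_id = out$person_id,
    total_health = out$total_total_health,
    bp_total = out$total_bp_inpatient + out$total_bp_outpatient,
    bp_inpatient = out$total_bp_inpatient,
    bp_outpatient = out$total_bp_outpatient,
    low_cost_total_health = out$n_inv_total_health == 0L,
    low_cost_bp_total = out$n_inv_bp_inpatient + out$n_inv_bp_outpatient == 0L,
    low_cost_bp_inpatient = out$n_inv_bp_inpatient == 0L,
    low_cost_bp_outpatient = out$n_inv_bp_outpatient == 0L
  )
}

#' Tukey upper fence and high-cost flags
#'
#' Computes `Q3 + 1.5 * IQR` (quartiles by linear interpolation between
#' order statistics, the type-7 convention) and flags values strictly above
#' the fence as upper outliers ("high-cost cases"). Only the upper fence is
#' used: health-care costs are bounded below by zero.
#'
#' @param values Numeric vector, `length >= 4`.
#' @return List with `q1`, `q3`, `iqr`, `fence`, `flags` (logical vector).
#' @export
#' @examples
#' tukey_upper_fence(c(1, 2, 3, 4, 100))
tukey_upper_fence <- function(values) {
  if (length(values) < 4) abort("need at least 4 values for a Tukey fence")
  if (any(is.na(values))) abort("values must not contain NA")
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  fence <- q[2] + 1.5 * iqr
  list(q1 = q[1], q3 = q[2], iqr = iqr, fence = fence,
       flags = values > fence)
}

#' Truncated mean after removing high- and low-cost cases
#'
#' Mean of the values that are neither flagged as upper outliers nor as
#' low-cost (no invoice submitted) cases.
#'
#' @param values Numeric vector.
#' @param high_flags,low_flags Logical vectors aligned with `values`.
#' @return Numeric scalar.
#' @export
truncated_mean <- function(values, high_flags, low_flags) {
  stopifnot(length(values) == length(high_flags),
            length(values) == length(low_flags))
  keep <- !high_flags & !low_flags
  if (!any(keep)) abort("no values survive truncation")
  mean(values[keep])
}

#' Sample skewness of a cost distribution
#'
#' Adjusted Fisher-Pearson standardised third moment (the `type = 2`
#' estimator, as reported by mainstream statistics software). Undefined for
#' constant vectors or fewer than 3 values; returns `NA` with a warning.
#'
#' @param values Numeric vector.
#' @return Numeric scalar, or `NA` when undefined.
#' @export
cost_skewness <- function(values) {
  if (length(values) < 3 || stats::sd(values) == 0) {
    warn("skewness undefined for constant or too-short vectors; returning NA")
    return(NA_real_)
  }
  e1071::skewness(values, type = 2)
}

#' Per-group cost summary table
#'
#' For every group (e.g. GCPS grade) and cost category, reports n, mean,
#' SD, quartiles, the Tukey upper fence, high-cost and low-cost case counts
#' and percentages, the truncated mean/SD (high- and low-cost cases
#' removed) and skewness before and after truncation, plus an `overall`
#' row per category. High-cost fences are computed once per category on
#' the whole cohort, not per group, so that per-group high-cost
#' percentages are comparable across groups.
#'
#' @param costs Tibble from [aggregate_costs()] (with `low_cost_*` flags).
#' @param groups Tibble `person_id`, `group` assigning each person to a
#'   group; persons missing from it are dropped.
#' @return Long tibble: `group`, `category`, `n`, `mean`, `sd`, `q1`, `q3`,
#'   `iqr`, `upper_fence`, `n_high_cost`, `pct_high_cost`, `n_low_cost`,
#'   `pct_low_cost`, `truncated_mean`, `truncated_sd`, `skew`,
#'   `skew_truncated`.
#' @export
cost_table_by_group <- function(costs, groups) {
  df <- dplyr::inner_join(costs, groups, by = "person_id")
  if (nrow(df) == 0) abort("no persons shared between costs and groups")
  out <- list()
  for (cat in cost_categories) {
    vals <- df[[cat]]
    fence <- tukey_upper_fence(vals)
    low <- df[[paste0("low_cost_", cat)]]
    high <- fence$flags
    grp_levels <- c("overall", sort(unique(as.character(df$group))))
    for (g in grp_levels) {
      sel <- if (g == "overall") rep(TRUE, nrow(df)) else
        as.character(df$group) == g
      v <- vals[sel]; h <- high[sel]; l <- low[sel]
      keep <- !h & !l
      out[[length(out) + 1L]] <- tibble(
        group = g, category = cat, n = sum(sel),
        mean = mean(v), sd = stats::sd(v),
        q1 = fence$q1, q3 = fence$q3, iqr = fence$iqr,
        upper_fence = fence$fence,
        n_high_cost = sum(h), pct_high_cost = 100 * mean(h),
        n_low_cost = sum(l), pct_low_cost = 100 * mean(l),
        truncated_mean = if (any(keep)) mean(v[keep]) else NA_real_,
        truncated_sd = if (sum(keep) > 1) stats::sd(v[keep]) else NA_real_,
        skew = if (length(v) >= 3 && stats::sd(v) > 0)
          e1071::skewness(v, type = 2) else NA_real_,
        skew_truncated = if (sum(keep) >= 3 && stats::sd(v[keep]) > 0)
          e1071::skewness(v[keep], type = 2) else NA_real_
      )
    }
  }
  dplyr::bind_rows(out)
}
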