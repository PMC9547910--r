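idx <- as.Date("2020-06-01")

test_that("an empty history yields all-zero features", {
  f <- cc_extract_features(empty_history(), idx)
  expect_equal(f$m_diag_count, 0L)
  expect_equal(f$f_diag_count, 0L)
  expect_equal(f$opioid_rx_count, 0L)
  expect_false(f$opioid_rx_pair_within_window)
  expect_equal(f$bp_sickleave_days, 0L)
  expect_equal(as.character(cc_classify(f)), "not_classifiable")
})

test_that("back-pain diagnosis records inside the window are counted", {
  h <- empty_history()
  h$diagnoses <- tibble::tibble(person_id = "A",
                                code = c("M54.5", "M54.5"),
                                date = c(idx - 5, idx - 35))
  expect_equal(cc_extract_features(h, idx)$m_diag_count, 2L)
  # same record repeated counts twice unless deduplication is requested
  h$diagnoses$date <- c(idx - 5, idx - 5)
  expect_equal(cc_extract_features(h, idx)$m_diag_count, 2L)
  expect_equal(cc_extract_features(h, idx,
                                   cc_config(dedupe_diagnoses = TRUE))$m_diag_count,
               1L)
})

test_that("window boundaries are closed: day 1 and day 365 count, day 366 not", {
  h <- empty_history()
  h$diagnoses <- tibble::tibble(person_id = "A", code = "M54.5",
                                date = idx - 364) # first day of the window
  expect_equal(cc_extract_features(h, idx)$m_diag_count, 1L)
  h$diagnoses$date <- idx
  expect_equal(cc_extract_features(h, idx)$m_diag_count, 1L)
  h$diagnoses$date <- idx - 365
  expect_equal(cc_extract_features(h, idx)$m_diag_count, 0L)
})

test_that("M-range and F-list code matching work on roots and prefixes", {
  h <- empty_history()
  h$diagnoses <- tibble::tibble(
    person_id = "A",
    code = c("M40.0", "M54.99", "M39.9", "M55.1", # range edges
             "F32.9", "F33.1", "F34.1", "F34.2",  # starred vs exact
             "F43.21", "F43.9", "F54", "F62.80", "F62.8"),
    date = rep(idx - 10, 13)
  )
  f <- cc_extract_features(h, idx)
  expect_equal(f$m_diag_count, 2L) # M40.0 and M54.99 only
  # F32*, F33*, F34.1 exact (not F34.2), F43.21 exact (not F43.9),
  # F54 prefix, F62.80 exact (not F62.8)
  expect_equal(f$f_diag_count, 6L)
})

test_that("the opioid pair flag matches a brute-force check over all pairs", {
  brute <- function(dates, gap) {
    if (length(dates) < 2) return(FALSE)
    any(abs(outer(as.integer(dates), as.integer(dates), "-"))[
      lower.tri(diag(length(dates)))] <= gap)
  }
  h <- empty_history()
  h$prescriptions <- tibble::tibble(person_id = "A",
                                    atc_code = c("N02AA05", "N02AX02"),
                                    date = c(idx - 10, idx - 210))
  expect_false(cc_extract_features(h, idx)$opioid_rx_pair_within_window)
  set.seed(7)
  for (i in 1:40) {
    k <- sample(0:5, 1)
    dates <- idx - sample(0:364, k, replace = TRUE)
    h$prescriptions <- tibble::tibble(person_id = "A",
                                      atc_code = rep("N02AA05", k),
                                      date = dates)
    f <- cc_extract_features(h, idx)
    expect_equal(f$opioid_rx_pair_within_window, brute(dates, 183L))
  }
  # non-opioid prescriptions never pair
  h$prescriptions <- tibble::tibble(person_id = "A",
                                    atc_code = c("M01AE01", "M01AE01"),
                                    date = c(idx - 10, idx - 12))
  expect_false(cc_extract_features(h, idx)$opioid_rx_pair_within_window)
})

test_that("sick-leave days sum the window overlap of attributed episodes", {
  h <- empty_history()
  h$sick_leave <- tibble::tibble(person_id = "A", start = idx - 100,
                                 end = idx - 51, attributed_code = "M51.1")
  expect_equal(cc_extract_features(h, idx)$bp_sickleave_days, 50L)
  # brute-force day-by-day oracle on random episodes, incl. partial overlap
  brute_days <- function(sl, idx, lb = 365L) {
    win <- seq(idx - lb + 1L, idx, by = "day")
    total <- 0L
    for (i in seq_len(nrow(sl))) {
      if (!grepl("^M(4[0-9]|5[0-4])", sl$attributed_code[i])) next
      days <- seq(sl$start[i], sl$end[i], by = "day")
      total <- total + sum(days %in% win)
    }
    total
  }
  set.seed(11)
  for (i in 1:25) {
    k <- sample(1:3, 1)
    start <- idx - sample(300:450, k, replace = TRUE)
    sl <- tibble::tibble(person_id = "A", start = start,
                         end = start + sample(0:80, k, replace = TRUE),
                         attributed_code = sample(c("M54.5", "M51.2", "J06.9"),
                                                  k, replace = TRUE))
    h$sick_leave <- sl
    expect_equal(cc_extract_features(h, idx)$bp_sickleave_days,
                 brute_days(sl, idx))
  }
})

test_that("classification follows the rules with precedence 3 > 2 > 1", {
  feat <- function(m = 0L, f = 0L, pair = FALSE, rx = if (pair) 2L else 0L,
                   sl = 0L) {
    tibble::tibble(m_diag_count = m, f_diag_count = f,
                   opioid_rx_count = rx,
                   opioid_rx_pair_within_window = pair,
                   bp_sickleave_days = sl)
  }
  expect_equal(as.character(cc_classify(feat(m = 2L, sl = 42L))), "3")
  expect_equal(as.character(cc_classify(feat(m = 2L, pair = TRUE))), "3")
  expect_equal(as.character(cc_classify(feat(m = 2L, f = 2L))), "2")
  expect_equal(as.character(cc_classify(feat(m = 2L, sl = 1L))), "2")
  expect_equal(as.character(cc_classify(feat(m = 2L, sl = 41L))), "2")
  expect_equal(as.character(cc_classify(feat(m = 2L))), "1")
  expect_equal(as.character(cc_classify(feat(m = 1L, sl = 60L, f = 5L))),
               "not_classifiable")
  # precedence: CC3 evidence wins even with CC2 evidence present
  expect_equal(as.character(cc_classify(feat(m = 2L, f = 4L, sl = 50L))), "3")
  expect_error(cc_classify(feat(m = -1L)))
  expect_error(cc_classify(feat(m = 2L, pair = TRUE, rx = 1L)))
})

test_that("classification is total and matches an independent rule oracle", {
  oracle <- function(m, f, pair, sl) {
    if (m < 2) return("not_classifiable")
    if (sl >= 42 || pair) return("3")
    if ((sl >= 1 && sl < 42) || f >= 2) return("2")
    "1"
  }
  set.seed(3)
  for (i in 1:200) {
    m <- sample(0:5, 1); f <- sample(0:4, 1)
    pair <- sample(c(TRUE, FALSE), 1); sl <- sample(0:90, 1)
    feats <- tibble::tibble(m_diag_count = m, f_diag_count = f,
                            opioid_rx_count = if (pair) 2L else sample(0:1, 1),
                            opioid_rx_pair_within_window = pair,
                            bp_sickleave_days = sl)
    expect_equal(as.character(cc_classify(feats)), oracle(m, f, pair, sl))
  }
})

test_that("adding opioid or sick-leave evidence never moves the class down", {
  ord <- function(cc) match(as.character(cc), c("1", "2", "3"))
  set.seed(5)
  for (i in 1:100) {
    feats <- tibble::tibble(
      m_diag_count = sample(2:4, 1), f_diag_count = sample(0:3, 1),
      opioid_rx_count = 0L, opioid_rx_pair_within_window = FALSE,
      bp_sickleave_days = sample(0:60, 1)
    )
    base <- ord(cc_classify(feats))
    more_sl <- feats; more_sl$bp_sickleave_days <- feats$bp_sickleave_days + 30L
    with_pair <- feats; with_pair$opioid_rx_count <- 2L
    with_pair$opioid_rx_pair_within_window <- TRUE
    expect_gte(ord(cc_classify(more_sl)), base)
    expect_gte(ord(cc_classify(with_pair)), base)
  }
})

test_that("dichotomisation maps 1,2 to non-severe and 3 to severe", {
  expect_equal(cc_severe(c("1", "2", "3")), c(FALSE, FALSE, TRUE))
  expect_error(cc_severe("not_classifiable"))
})

test_that("vectorised classification equals the per-person path", {
  pop <- generate_population(generator_config(n_persons = 150, seed = 23))
  vec <- classify_cc(pop)
  enr <- pop$enrolment
  for (i in sample(nrow(enr), 30)) {
    pid <- enr$person_id[i]
    h <- list(diagnoses = pop$diagnoses[pop$diagnoses$person_id == pid, ],
              prescriptions = pop$prescriptions[
                pop$prescriptions$person_id == pid, ],
              sick_leave = pop$sick_leave[pop$sick_leave$person_id == pid, ])
    anchor <- if (is.na(enr$invitation_date[i])) enr$enrolment_date[i] else
      enr$invitation_date[i]
    f1 <- cc_extract_features(h, anchor)
    expect_equal(as.character(cc_classify(f1)),
                 as.character(vec$cc[vec$person_id == pid]))
  }
})
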