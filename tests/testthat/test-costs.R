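test_that("cost aggregation sums CPI-adjusted amounts inside the window", {
  d <- as.Date("2020-06-01")
  enr <- tibble::tibble(person_id = c("A", "B"),
                        enrolment_date = c(d, d))
  no_inv <- tibble::tibble(person_id = character(),
                           date = as.Date(character()),
                           category = character(), amount = double(),
                           year = integer())
  z <- aggregate_costs(no_inv, enr, cpi_table = NULL)
  expect_equal(z$total_health, c(0, 0))
  expect_true(all(z$low_cost_bp_total))

  inv <- tibble::tibble(
    person_id = c("A", "A", "A"),
    date = c(d - 10, d - 20, d - 400), # third lies outside the window
    category = c("bp_outpatient", "bp_outpatient", "bp_outpatient"),
    amount = c(100, 50, 999),
    year = c(2020L, 2020L, 2019L)
  )
  v <- aggregate_costs(inv, enr, cpi_table = NULL)
  expect_equal(v$bp_outpatient[v$person_id == "A"], 150)
  expect_equal(v$bp_total[v$person_id == "A"], 150)
  expect_equal(v$bp_inpatient[v$person_id == "A"], 0)
  expect_false(v$low_cost_bp_total[v$person_id == "A"])
  expect_true(v$low_cost_bp_inpatient[v$person_id == "A"])
  expect_true(v$low_cost_total_health[v$person_id == "A"])
})

test_that("CPI adjustment is a simple index ratio with hard errors", {
  expect_equal(cpi_adjust(100, 2020, base_year = 2020), 100)
  tbl <- tibble::tibble(year = c(2019L, 2020L), cpi = c(100, 105))
  expect_equal(cpi_adjust(100, 2019L, tbl, 2020L), 105)
  expect_error(cpi_adjust(100, 2005L, tbl, 2020L), "missing")
  expect_error(cpi_adjust(100, 2019L, tbl[0, ], 2020L), "empty")
})

test_that("Tukey fence uses type-7 quartiles and flags strict exceedance", {
  f <- tukey_upper_fence(c(1, 2, 3, 4, 100))
  # sorted n = 5: Q1 = 2nd order statistic = 2, Q3 = 4th = 4 (type 7)
  expect_equal(f$q1, 2)
  expect_equal(f$q3, 4)
  expect_equal(f$fence, 4 + 1.5 * 2)
  expect_equal(f$flags, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  const <- tukey_upper_fence(rep(7, 10))
  expect_equal(const$iqr, 0)
  expect_false(any(const$flags))
  below <- tukey_upper_fence(c(1, 2, 3, 4))
  expect_false(any(below$flags))
  expect_error(tukey_upper_fence(c(1, 2, 3)), "at least 4")
})

test_that("the fence is equivariant under shift and positive scaling", {
  set.seed(31)
  for (i in 1:20) {
    v <- stats::rlnorm(50)
    c0 <- stats::runif(1, -5, 5)
    s0 <- stats::runif(1, 0.1, 10)
    f <- tukey_upper_fence(v)
    expect_equal(tukey_upper_fence(v + c0)$fence, f$fence + c0)
    expect_equal(tukey_upper_fence(v * s0)$fence, f$fence * s0)
    expect_equal(tukey_upper_fence(v + c0)$flags, f$flags)
    expect_equal(tukey_upper_fence(v * s0)$flags, f$flags)
  }
})

test_that("low-cost flags are presence-based and category-specific", {
  d <- as.Date("2020-06-01")
  enr <- tibble::tibble(person_id = "A", enrolment_date = d)
  inv <- tibble::tibble(person_id = "A", date = d - 5,
                        category = "total_health", amount = 0.01,
                        year = 2020L)
  v <- aggregate_costs(inv, enr, cpi_table = NULL)
  expect_false(v$low_cost_total_health) # one 1-cent invoice still counts
  expect_true(v$low_cost_bp_total)      # bp-low while total-health-present
})

test_that("the truncated mean removes exactly the flagged cases", {
  v <- c(0, 10, 20, 1e6)
  high <- c(FALSE, FALSE, FALSE, TRUE)
  low <- c(TRUE, FALSE, FALSE, FALSE)
  expect_equal(truncated_mean(v, high, low), 15)
  expect_equal(truncated_mean(v, rep(FALSE, 4), rep(FALSE, 4)), mean(v))
  expect_error(truncated_mean(v, rep(TRUE, 4), rep(FALSE, 4)), "survive")
})

test_that("removing only above-fence values never increases the mean", {
  set.seed(37)
  for (i in 1:30) {
    v <- stats::rlnorm(60, sdlog = 1.5)
    f <- tukey_upper_fence(v)
    if (any(f$flags)) {
      expect_lte(truncated_mean(v, f$flags, rep(FALSE, length(v))), mean(v))
    }
  }
})

test_that("skewness matches a brute-force moment computation", {
  expect_equal(cost_skewness(c(1, 2, 3)), 0)
  brute <- function(x) {
    n <- length(x)
    g1 <- mean((x - mean(x))^3) / (mean((x - mean(x))^2))^1.5
    g1 * sqrt(n * (n - 1)) / (n - 2) # adjusted Fisher-Pearson
  }
  set.seed(41)
  for (i in 1:10) {
    x <- stats::rlnorm(30)
    expect_equal(cost_skewness(x), brute(x))
  }
  expect_warning(expect_true(is.na(cost_skewness(rep(3, 5)))), "undefined")
})

test_that("truncation reduces lognormal skewness in almost all replicates", {
  set.seed(43)
  reduced <- replicate(300, {
    v <- stats::rlnorm(500, sdlog = 1.2)
    f <- tukey_upper_fence(v)
    keep <- v[!f$flags]
    abs(cost_skewness(keep)) < abs(cost_skewness(v))
  })
  expect_gte(mean(reduced), 0.95)
})

test_that("per-group cost summaries match hand enumeration", {
  costs <- tibble::tibble(
    person_id = sprintf("P%d", 1:6),
    total_health = c(100, 200, 300, 400, 500, 600),
    bp_total = c(10, 0, 30, 40, 50, 60),
    bp_inpatient = rep(0, 6),
    bp_outpatient = c(10, 0, 30, 40, 50, 60),
    low_cost_total_health = rep(FALSE, 6),
    low_cost_bp_total = c(FALSE, TRUE, rep(FALSE, 4)),
    low_cost_bp_inpatient = rep(TRUE, 6),
    low_cost_bp_outpatient = c(FALSE, TRUE, rep(FALSE, 4))
  )
  groups <- tibble::tibble(person_id = costs$person_id,
                           group = rep(c("g1", "g2"), each = 3))
  tab <- cost_table_by_group(costs, groups)
  th_g1 <- tab[tab$group == "g1" & tab$category == "total_health", ]
  expect_equal(th_g1$n, 3L)
  expect_equal(th_g1$mean, 200)
  expect_equal(th_g1$sd, 100)
  bp_all <- tab[tab$group == "overall" & tab$category == "bp_total", ]
  expect_equal(bp_all$n_low_cost, 1L)
  expect_equal(bp_all$truncated_mean, mean(c(10, 30, 40, 50, 60)))
  # constant single-group case
  cconst <- costs
  cconst$total_health <- rep(42, 6)
  tc <- cost_table_by_group(cconst,
                            tibble::tibble(person_id = costs$person_id,
                                           group = "only"))
  th <- tc[tc$group == "only" & tc$category == "total_health", ]
  expect_equal(th$mean, 42)
  expect_equal(th$sd, 0)
  expect_true(is.na(th$skew))
})
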