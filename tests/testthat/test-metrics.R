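test_that("confusion matrices tabulate predicted x observed correctly", {
  m <- confusion_matrix(rep("a", 5), rep("a", 5), labels = c("a", "b"))
  expect_equal(diag(m$counts), c(a = 5L, b = 0L))
  pred <- c("x", "x", "y", "y")
  obs <- c("x", "y", "y", "x")
  m2 <- confusion_matrix(pred, obs, labels = c("x", "y"))
  expect_equal(as.vector(m2$counts), c(1L, 1L, 1L, 1L))
  expect_equal(m2$n, 4L)
  expect_error(confusion_matrix(character(), character()), "empty")
  expect_error(confusion_matrix("a", c("a", "b")), "equal length")
  expect_error(confusion_matrix("a", "c", labels = c("a", "b")), "outside")
})

test_that("sensitivity, specificity and proportion correct behave at edges", {
  m <- confusion_from_counts(tp = 10, fp = 0, fn = 0, tn = 5)
  expect_equal(sensitivity(m), 1)
  expect_equal(specificity(m), 1)
  expect_equal(proportion_correct(m), 1)
  expect_equal(mcc(m), 1)
  none_pos <- confusion_from_counts(0, 3, 0, 7)
  expect_error(sensitivity(none_pos), "undefined")
  expect_warning(expect_equal(mcc(none_pos), 0), "degenerate")
})

test_that("MCC equals the Pearson correlation of the binary codings", {
  set.seed(9)
  for (i in 1:20) {
    n <- 200
    pred <- sample(c(TRUE, FALSE), n, replace = TRUE)
    obs <- ifelse(stats::runif(n) < 0.7, pred, !pred)
    m <- confusion_matrix(ifelse(pred, "pos", "neg"),
                          ifelse(obs, "pos", "neg"),
                          labels = c("pos", "neg"))
    expect_equal(mcc(m), stats::cor(pred, obs))
  }
})

test_that("MCC is symmetric under joint label swap and antisymmetric under
           one-sided swap", {
  m <- confusion_from_counts(40, 12, 8, 60)
  swapped_both <- confusion_from_counts(60, 8, 12, 40)
  swapped_rows <- confusion_from_counts(8, 60, 40, 12)
  expect_equal(mcc(m), mcc(swapped_both))
  expect_equal(mcc(m), -mcc(swapped_rows))
})

test_that("kappa weightings coincide on 2 x 2 tables and for perfect raters", {
  m <- confusion_from_counts(40, 12, 8, 60)
  k_none <- cohen_kappa(m, "none")$estimate
  expect_equal(cohen_kappa(m, "linear")$estimate, k_none)
  expect_equal(cohen_kappa(m, "quadratic")$estimate, k_none)
  ident <- confusion_matrix(c("1", "2", "3"), c("1", "2", "3"),
                            labels = c("1", "2", "3"))
  expect_equal(cohen_kappa(ident)$estimate, 1)
})

test_that("unweighted kappa agrees with the e1071 implementation", {
  set.seed(13)
  for (i in 1:10) {
    counts <- matrix(sample(1:60, 9, replace = TRUE), 3)
    m <- structure(list(counts = counts, labels = c("1", "2", "3"),
                        n = sum(counts)), class = "confusion_matrix")
    expect_equal(cohen_kappa(m, "none")$estimate,
                 e1071::classAgreement(counts)$kappa)
  }
})

test_that("weighted kappa matches a brute-force Po/Pe enumeration", {
  brute_wkappa <- function(counts, w) {
    n <- sum(counts)
    po <- 0; pe <- 0
    k <- nrow(counts)
    for (i in 1:k) for (j in 1:k) {
      po <- po + w[i, j] * counts[i, j] / n
      pe <- pe + w[i, j] * sum(counts[i, ]) * sum(counts[, j]) / n^2
    }
    (po - pe) / (1 - pe)
  }
  set.seed(17)
  for (wt in c("linear", "quadratic")) {
    k <- 3
    d <- abs(outer(1:k, 1:k, "-")) / (k - 1)
    w <- if (wt == "linear") 1 - d else 1 - d^2
    for (i in 1:10) {
      counts <- matrix(sample(0:50, 9, replace = TRUE), 3)
      counts[1, 1] <- counts[1, 1] + 5L # avoid fully degenerate draws
      m <- structure(list(counts = counts, labels = c("1", "2", "3"),
                          n = sum(counts)), class = "confusion_matrix")
      expect_equal(cohen_kappa(m, wt)$estimate, brute_wkappa(counts, w))
    }
  }
})

test_that("kappa and MCC are near zero for independent random labels", {
  set.seed(21)
  n <- 10000
  pred <- sample(c("severe", "non-severe"), n, TRUE, prob = c(0.3, 0.7))
  obs <- sample(c("severe", "non-severe"), n, TRUE, prob = c(0.35, 0.65))
  m <- confusion_matrix(pred, obs, labels = c("severe", "non-severe"))
  expect_lt(abs(mcc(m)), 4 / sqrt(n))
  expect_lt(abs(cohen_kappa(m)$estimate), 4 / sqrt(n))
})

test_that("kappa confidence intervals contain the estimate and shrink with n", {
  m_small <- confusion_from_counts(20, 10, 12, 30)
  m_big <- confusion_from_counts(200, 100, 120, 300)
  for (m in list(m_small, m_big)) {
    k <- cohen_kappa(m)
    expect_lt(k$conf_int[1], k$estimate)
    expect_gt(k$conf_int[2], k$estimate)
  }
  expect_lt(diff(cohen_kappa(m_big)$conf_int),
            diff(cohen_kappa(m_small)$conf_int))
})

test_that("Spearman's rho handles concordance, reversal and ties", {
  expect_equal(spearman_rho(1:6, c(2, 3, 5, 7, 11, 13))$estimate, 1)
  expect_equal(spearman_rho(1:4, 4:1)$estimate, -1)
  # tied 6-pair example against an explicit rank-then-Pearson oracle
  x <- c(1, 2, 2, 3, 3, 3)
  y <- c(1, 1, 2, 2, 3, 3)
  oracle <- stats::cor(rank(x), rank(y))
  expect_equal(spearman_rho(x, y)$estimate, oracle)
  ci <- spearman_rho(x, y)$conf_int
  expect_lt(ci[1], oracle)
  expect_gt(ci[2], oracle)
})

test_that("verbal interpretation bands reproduce the published examples", {
  expect_equal(interpret_metric("mcc", 0.304), "fair")
  expect_equal(interpret_metric("rho", 0.343), "moderate")
  expect_equal(interpret_metric("kappa", 0.307), "fair")
  expect_equal(interpret_metric("rho", 0.05), "weak")
  expect_equal(interpret_metric("rho", 0.9), "very strong")
  expect_equal(interpret_metric("kappa", 0.15), "poor")
  expect_equal(interpret_metric("kappa", 0.95), "almost perfect")
  expect_equal(interpret_metric("mcc", 0.005), "negligible")
  expect_equal(interpret_metric("mcc", 0.65), "moderately strong")
  # lower band edges are inclusive
  expect_equal(interpret_metric("mcc", 0.3), "fair")
  expect_equal(interpret_metric("kappa", 0.21), "fair")
  expect_equal(interpret_metric("rho", 0.31), "moderate")
})

test_that("a validity report recomputes from a brute-force per-person tally", {
  set.seed(29)
  n <- 500
  cc3 <- sample(c("1", "2", "3"), n, TRUE)
  g3 <- sample(c("1", "2", "3"), n, TRUE, prob = c(0.5, 0.3, 0.2))
  rep_ <- validity_report(cc3, g3)
  # brute-force the 2x2 cells by explicit counting
  tp <- sum(cc3 == "3" & g3 %in% c("2", "3"))
  fp <- sum(cc3 == "3" & g3 == "1")
  fn <- sum(cc3 != "3" & g3 %in% c("2", "3"))
  tn <- sum(cc3 != "3" & g3 == "1")
  expect_equal(rep_$matrix2$counts[1, 1], tp)
  expect_equal(rep_$matrix2$counts[1, 2], fp)
  expect_equal(rep_$matrix2$counts[2, 1], fn)
  expect_equal(rep_$matrix2$counts[2, 2], tn)
  expect_equal(rep_$sensitivity, tp / (tp + fn))
  expect_equal(rep_$specificity, tn / (tn + fp))
  expect_equal(rep_$correct, (tp + tn) / n)
  # 3x3 diagonal tally
  for (i in 1:3) {
    expect_equal(rep_$matrix3$counts[i, i],
                 sum(cc3 == as.character(i) & g3 == as.character(i)))
  }
})
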