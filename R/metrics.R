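#' Cross-tabulate predicted vs observed severity
#'
#' Builds a k x k confusion matrix with rows = predicted and columns =
#' observed category, in the order given by `labels`. For the 2 x 2 case
#' the first label is the positive ("severe") class, so
#' `counts[1, 1]` is TP, `counts[1, 2]` FP, `counts[2, 1]` FN and
#' `counts[2, 2]` TN.
#'
#' @param predicted,observed Equal-length vectors whose values all appear
#'   in `labels`.
#' @param labels Ordered category labels (defaults to the sorted union of
#'   the observed values).
#' @return Object of class `confusion_matrix`: list with `counts`
#'   (integer matrix), `labels`, `n`.
#' @export
#' @examples
#' confusion_matrix(c("a", "a", "b"), c("a", "b", "b"), labels = c("a", "b"))
confusion_matrix <- function(predicted, observed, labels = NULL) {
  if (length(predicted) != length(observed)) {
    abort("predicted and observed must have equal length")
  }
  if (length(predicted) == 0) abort("cannot tabulate empty vectors")
  predicted <- as.character(predicted)
  observed <- as.character(observed)
  if (is.null(labels)) labels <- sort(unique(c(predicted, observed)))
  labels <- as.character(labels)
  if (length(labels) < 2) abort("at least two category labels are required")
  bad <- setdiff(unique(c(predicted, observed)), labels)
  if (length(bad) > 0) {
    abort(paste0("values outside labels: ", paste(bad, collapse = ", ")))
  }
  counts <- table(factor(predicted, levels = labels),
                  factor(observed, levels = labels))
  counts <- matrix(as.integer(counts), nrow = length(labels),
                   dimnames = list(predicted = labels, observed = labels))
  structure(list(counts = counts, labels = labels, n = sum(counts)),
            class = "confusion_matrix")
}

#' Build a 2 x 2 confusion matrix from the four cell counts
#'
#' Convenience constructor for recomputing published tables: give TP, FP,
#' FN, TN directly (positive class first).
#'
#' @param tp,fp,fn,tn Non-negative integer cell counts.
#' @param labels Two labels, positive class first.
#' @return A `confusion_matrix`.
#' @export
#' @examples
#' confusion_from_counts(401, 392, 333, 1270)
confusion_from_counts <- function(tp, fp, fn, tn,
                                  labels = c("severe", "non-severe")) {
  stopifnot(length(labels) == 2, tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  counts <- matrix(as.integer(c(tp, fn, fp, tn)), nrow = 2,
                   dimnames = list(predicted = labels, observed = labels))
  structure(list(counts = counts, labels = labels, n = sum(counts)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = predicted, columns = observed), n =",
      x$n, "\n")
  print(stats::addmargins(x$counts))
  invisible(x)
}

check_2x2 <- function(m) {
  if (!inherits(m, "confusion_matrix")) abort("expected a confusion_matrix")
  if (length(m$labels) != 2) {
    abort("this metric is defined for 2 x 2 confusion matrices")
  }
  list(tp = m$counts[1, 1], fp = m$counts[1, 2],
       fn = m$counts[2, 1], tn = m$counts[2, 2])
}

#' Sensitivity of a 2 x 2 confusion matrix
#'
#' Proportion of truly severe cases the classifier identifies:
#' TP / (TP + FN).
#'
#' @param m A 2 x 2 [confusion_matrix()], positive class first.
#' @return Proportion in \[0, 1\].
#' @export
sensitivity <- function(m) {
  c2 <- check_2x2(m)
  if (c2$tp + c2$fn == 0) abort("no observed positive cases: sensitivity undefined")
  c2$tp / (c2$tp + c2$fn)
}

#' Specificity of a 2 x 2 confusion matrix
#'
#' Proportion of truly non-severe cases classified non-severe:
#' TN / (TN + FP).
#'
#' @inheritParams sensitivity
#' @return Proportion in \[0, 1\].
#' @export
specificity <- function(m) {
  c2 <- check_2x2(m)
  if (c2$tn + c2$fp == 0) abort("no observed negative cases: specificity undefined")
  c2$tn / (c2$tn + c2$fp)
}

#' Proportion of correctly classified cases
#'
#' Trace of the confusion matrix over its total; defined for any k.
#'
#' @param m A [confusion_matrix()].
#' @return Proportion in \[0, 1\].
#' @export
proportion_correct <- function(m) {
  if (!inherits(m, "confusion_matrix")) abort("expected a confusion_matrix")
  sum(diag(m$counts)) / m$n
}

#' Matthews correlation coefficient of a 2 x 2 confusion matrix
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, the phi-style
#' correlation between predicted and observed class, robust to class
#' imbalance. When any margin is zero the coefficient is undefined; the
#' function then returns 0 with a warning so that stochastic simulations
#' never crash on a degenerate draw.
#'
#' @inheritParams sensitivity
#' @return Value in \[-1, 1\].
#' @export
mcc <- function(m) {
  c2 <- check_2x2(m)
  margins <- with(c2, c(tp + fp, tp + fn, tn + fp, tn + fn))
  if (any(margins == 0)) {
    warn("degenerate margin in confusion matrix: MCC undefined, returning 0")
    return(0)
  }
  with(c2, (tp * tn - fp * fn) / sqrt(prod(margins)))
}

kappa_weight_matrix <- function(k, weights = c("none", "linear", "quadratic")) {
  weights <- match.arg(weights)
  d <- abs(outer(seq_len(k), seq_len(k), "-"))
  switch(weights,
         none = (d == 0) * 1,
         linear = 1 - d / (k - 1),
         quadratic = 1 - (d / (k - 1))^2)
}

#' Cohen's (weighted) kappa with asymptotic confidence interval
#'
#' Chance-corrected agreement `(Po - Pe) / (1 - Pe)` between the row and
#' column classifications of a k x k confusion matrix. For ordinal scales
#' linear or quadratic weights credit partial agreement; for a 2 x 2 table
#' every weighting coincides with the unweighted kappa. The standard error
#' is the large-sample (Fleiss-Cohen-Everitt) formula for weighted kappa,
#' and the interval is `estimate +/- z * SE`.
#'
#' @param m A [confusion_matrix()].
#' @param weights `"none"`, `"linear"` or `"quadratic"`.
#' @param conf_level Confidence level for the interval.
#' @return List with `estimate`, `se`, `conf_int` (length-2 vector),
#'   `weights`.
#' @export
#' @examples
#' cohen_kappa(confusion_from_counts(401, 392, 333, 1270))
cohen_kappa <- function(m, weights = c("none", "linear", "quadratic"),
                        conf_level = 0.95) {
  if (!inherits(m, "confusion_matrix")) abort("expected a confusion_matrix")
  weights <- match.arg(weights)
  if (m$n == 0) abort("empty confusion matrix")
  k <- length(m$labels)
  w <- kappa_weight_matrix(k, weights)
  p <- m$counts / m$n
  pr <- rowSums(p)
  pc <- colSums(p)
  po <- sum(w * p)
  pe <- sum(w * outer(pr, pc))
  if (isTRUE(all.equal(pe, 1))) {
    abort("expected agreement is 1: kappa undefined")
  }
  kap <- (po - pe) / (1 - pe)
  # expected weights of each row/column under the margins
  wi <- as.vector(w %*% pc)   # E[w | predicted = i]
  wj <- as.vector(t(w) %*% pr) # E[w | observed = j]
  term <- (w * (1 - pe) -
             (outer(wi, rep(1, k)) + outer(rep(1, k), wj)) * (1 - po))^2
  var_k <- (sum(p * term) - (po * pe - 2 * pe + po)^2) /
    (m$n * (1 - pe)^4)
  se <- sqrt(max(var_k, 0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(estimate = kap, se = se,
       conf_int = c(kap - z * se, kap + z * se),
       weights = weights)
}

#' Spearman rank correlation with a Fisher-z confidence interval
#'
#' Rank correlation with average ranks for ties (the ordinal association
#' between the two classifications), plus an approximate confidence
#' interval from the Fisher z-transform with the Fieller-Hartley-Pearson
#' variance `1.06 / (n - 3)`.
#'
#' @param x,y Equal-length ordinal vectors (factors, integers or anything
#'   `rank()` accepts).
#' @param conf_level Confidence level.
#' @return List with `estimate`, `conf_int`, `n`.
#' @export
spearman_rho <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  n <- length(x)
  if (n < 4) abort("need at least 4 pairs for a confidence interval")
  if (is.factor(x)) x <- as.integer(x)
  if (is.factor(y)) y <- as.integer(y)
  rho <- stats::cor(x, y, method = "spearman")
  z <- atanh(rho)
  se_z <- sqrt(1.06 / (n - 3))
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(estimate = rho,
       conf_int = tanh(c(z - q * se_z, z + q * se_z)),
       n = n)
}

# Verbal interpretation bands as printed for the three association scales.
# Each band is inclusive at the lower edge of its printed interval.
interpretation_bands <- list(
  rho = list(cuts = c(0.1, 0.31, 0.51, 0.81),
             labels = c("weak", "modest", "moderate", "strong",
                        "very strong")),
  kappa = list(cuts = c(0.21, 0.41, 0.61, 0.81),
               labels = c("poor", "fair", "moderate", "substantial",
                          "almost perfect")),
  mcc = list(cuts = c(0.01, 0.3, 0.6, 0.8),
             labels = c("negligible", "very weak", "fair",
                        "moderately strong", "very strong"))
)

#' Verbal interpretation of an association metric
#'
#' Maps a metric value onto the published verbal band for that scale:
#' Spearman's rho (weak/modest/moderate/strong/very strong), Cohen's kappa
#' (poor/fair/moderate/substantial/almost perfect) or MCC (very weak/fair/
#' moderately strong/very strong, with values below 0.01 "negligible").
#'
#' @param metric `"rho"`, `"kappa"` or `"mcc"`.
#' @param value Numeric scalar.
#' @return Character scalar, the band label.
#' @export
#' @examples
#' interpret_metric("mcc", 0.304)   # "fair"
#' interpret_metric("rho", 0.343)   # "moderate"
interpret_metric <- function(metric = c("rho", "kappa", "mcc"), value) {
  metric <- match.arg(metric)
  stopifnot(is.numeric(value), length(value) == 1, !is.na(value))
  band <- interpretation_bands[[metric]]
  band$labels[findInterval(value, band$cuts) + 1L]
}

#' Full criterion-validity metric report for a severity comparison
#'
#' Computes, from vectors of predicted (chronicity class) and observed
#' (GCPS) severity, the 3 x 3 ordinal comparison (Spearman's rho and
#' weighted kappa with confidence intervals) and the dichotomised 2 x 2
#' comparison (sensitivity, specificity, proportion correct, MCC and
#' kappa), each with its verbal interpretation band.
#'
#' @param cc3 Vector of predicted classes in `{1, 2, 3}`.
#' @param grade3 Vector of observed collapsed grades in `{1, 2, 3}`.
#' @param kappa_weights Weighting for the 3 x 3 kappa.
#' @return List of class `validity_report`: `matrix3`, `rho`, `kappa3`,
#'   `matrix2`, `sensitivity`, `specificity`, `correct`, `mcc`, `kappa2`,
#'   `bands`, `n`.
#' @export
validity_report <- function(cc3, grade3, kappa_weights = "linear") {
  m3 <- confusion_matrix(cc3, grade3, labels = c("1", "2", "3"))
  rho <- spearman_rho(factor(cc3, levels = c("1", "2", "3")),
                      factor(grade3, levels = c("1", "2", "3")))
  kap3 <- cohen_kappa(m3, weights = kappa_weights)
  pred_sev <- ifelse(as.character(cc3) == "3", "severe", "non-severe")
  obs_sev <- ifelse(as.character(grade3) %in% c("2", "3"),
                    "severe", "non-severe")
  m2 <- confusion_matrix(pred_sev, obs_sev, labels = c("severe", "non-severe"))
  sens <- sensitivity(m2)
  spec <- specificity(m2)
  corr <- proportion_correct(m2)
  mcc2 <- mcc(m2)
  kap2 <- cohen_kappa(m2, weights = "none")
  structure(
    list(matrix3 = m3, rho = rho, kappa3 = kap3,
         matrix2 = m2, sensitivity = sens, specificity = spec,
         correct = corr, mcc = mcc2, kappa2 = kap2,
         bands = list(rho = interpret_metric("rho", rho$estimate),
                      kappa3 = interpret_metric("kappa", kap3$estimate),
                      mcc = interpret_metric("mcc", mcc2),
                      kappa2 = interpret_metric("kappa", kap2$estimate)),
         n = m3$n),
    class = "validity_report"
  )
}

# Display rounding used in rendered reports: proportions to one decimal
# percent, correlations to three decimals. Internal values stay unrounded.
fmt_pct <- function(p) sprintf("%.1f%%", 100 * p)
fmt_cor <- function(r) sprintf("%.3f", r)

#' Render a 2 x 2 confusion matrix report as text
#'
#' Produces the table shape used to publish the dichotomised comparison:
#' the four cells with margins, then sensitivity, specificity, proportion
#' correctly predicted (one-decimal percents), MCC and kappa with its
#' confidence interval (three decimals). Every printed number is the
#' corresponding unrounded metric rounded by this display rule.
#'
#' @param m A 2 x 2 [confusion_matrix()].
#' @param title Heading line.
#' @return Character vector of report lines (invisibly printed with `cat`
#'   when called interactively via `print`).
#' @export
render_confusion_report <- function(m, title = "Predicted vs observed severity") {
  c2 <- check_2x2(m)
  kap <- cohen_kappa(m)
  lines <- c(
    title,
    sprintf("%-22s %10s %12s %8s", "", "Observed +", "Observed -", "Total"),
    sprintf("%-22s %10s %12s %8d", paste0("Predicted ", m$labels[1]),
            paste0("TP: ", c2$tp), paste0("FP: ", c2$fp), c2$tp + c2$fp),
    sprintf("%-22s %10s %12s %8d", paste0("Predicted ", m$labels[2]),
            paste0("FN: ", c2$fn), paste0("TN: ", c2$tn), c2$fn + c2$tn),
    sprintf("%-22s %10d %12d %8d", "Total", c2$tp + c2$fn, c2$fp + c2$tn, m$n),
    paste0("Sensitivity          ", fmt_pct(sensitivity(m))),
    paste0("Specificity          ", fmt_pct(specificity(m))),
    paste0("Correctly predicted  ", fmt_pct(proportion_correct(m))),
    paste0("MCC                  ", fmt_cor(mcc(m))),
    paste0("Cohen's kappa        ", fmt_cor(kap$estimate),
           " (95% CI: ", fmt_cor(kap$conf_int[1]), "-",
           fmt_cor(kap$conf_int[2]), ")")
  )
  lines
}

#' @export
print.validity_report <- function(x, ...) {
  cat("Criterion validity of predicted vs observed severity, n =", x$n, "\n\n")
  cat("3-level comparison: rho", fmt_cor(x$rho$estimate),
      paste0("(", x$bands$rho, ")"),
      " weighted kappa", fmt_cor(x$kappa3$estimate),
      paste0("(", x$bands$kappa3, ")"), "\n\n")
  cat(render_confusion_report(x$matrix2), sep = "\n")
  invisible(x)
}
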