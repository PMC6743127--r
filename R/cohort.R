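#' Difference of two proportions with a continuity-corrected Wald CI
#'
#' Computes the difference in percentage points between two independent
#' proportions with a 95% Wald interval including a continuity correction:
#' `delta +/- [z * sqrt(p1 q1 / n1 + p2 q2 / n2) + (1/n1 + 1/n2)/2] * 100`,
#' clipped to \[-100, 100\]. A two-sided chi-squared p-value (with Yates
#' correction, reconstructed from the implied 2x2 counts) is attached.
#' Inputs may be counts (`x1`, `x2`, preferred) or proportions (`p1`,
#' `p2`, possibly rounded as printed in a report).
#'
#' @param n1,n2 Sample sizes.
#' @param x1,x2 Successes (optional if `p1`, `p2` given).
#' @param p1,p2 Proportions in \[0, 1\] (optional if counts given).
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble: `p1`, `n1`, `p2`, `n2`, `delta` (percentage
#'   points), `ci_low`, `ci_high`, `p_value`, `method`.
#' @export
#' @examples
#' prop_diff_ci(n1 = 74, p1 = 0.527, n2 = 29, p2 = 0.138)
prop_diff_ci <- function(n1, n2, x1 = NULL, x2 = NULL, p1 = NULL, p2 = NULL,
                         conf_level = 0.95) {
  if (n1 < 1 || n2 < 1) {
    stop_gusnet("sample sizes must be at least 1", class = "gusnet_domain_error")
  }
  if (is.null(p1)) {
    if (is.null(x1)) stop_gusnet("supply x1 or p1", class = "gusnet_domain_error")
    p1 <- x1 / n1
  }
  if (is.null(p2)) {
    if (is.null(x2)) stop_gusnet("supply x2 or p2", class = "gusnet_domain_error")
    p2 <- x2 / n2
  }
  if (p1 < 0 || p1 > 1 || p2 < 0 || p2 > 1) {
    stop_gusnet("proportions must lie in [0, 1]", class = "gusnet_domain_error")
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  delta <- 100 * (p1 - p2)
  half <- (z * sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2) +
             (1 / n1 + 1 / n2) / 2) * 100
  ci_low <- max(-100, delta - half)
  ci_high <- min(100, delta + half)

  # p-value from the implied 2x2 table (counts rounded if p was printed)
  k1 <- if (is.null(x1)) round(p1 * n1) else x1
  k2 <- if (is.null(x2)) round(p2 * n2) else x2
  tab <- rbind(c(k1, n1 - k1), c(k2, n2 - k2))
  p_value <- if (any(colSums(tab) == 0)) {
    NA_real_
  } else {
    suppressWarnings(stats::chisq.test(tab)$p.value)
  }

  tibble::tibble(
    p1 = p1, n1 = n1, p2 = p2, n2 = n2,
    delta = delta, ci_low = ci_low, ci_high = ci_high,
    p_value = p_value,
    method = "Wald with continuity correction"
  )
}

#' Pearson chi-squared test on a contingency table
#'
#' Pearson statistic without continuity correction,
#' `df = (r - 1)(c - 1)`, for baseline-characteristic comparisons across
#' design groups.
#'
#' @param table An r x c matrix of counts (at least 2x2).
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
chi_square_test <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2) {
    stop_gusnet("need at least a 2x2 table", class = "gusnet_domain_error")
  }
  if (any(table < 0)) {
    stop_gusnet("counts must be non-negative", class = "gusnet_domain_error")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop_gusnet("degenerate table: a row or column marginal is zero",
                class = "gusnet_degenerate_table")
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = unname(ht$p.value))
}

#' One-way ANOVA reconstructed from group summary statistics
#'
#' Computes the classic one-way ANOVA F test from per-group means,
#' standard deviations and sizes, as needed when only a summary table is
#' available: between-groups sum of squares from the means and sizes,
#' within-groups from the sds.
#'
#' @param means,sds,ns Numeric vectors, one entry per group (k >= 2
#'   groups, each `n >= 2`, `sd > 0`).
#' @return A one-row tibble: `F`, `df1`, `df2`, `p_value`.
#' @export
#' @examples
#' anova_from_summary(means = c(68.6, 69, 67.6),
#'                    sds = c(12.3, 10.4, 12.4),
#'                    ns = c(27, 28, 19))
anova_from_summary <- function(means, sds, ns) {
  k <- length(means)
  if (length(sds) != k || length(ns) != k) {
    stop_gusnet("means, sds and ns must have the same length",
                class = "gusnet_domain_error")
  }
  if (k < 2) {
    stop_gusnet("need at least 2 groups", class = "gusnet_domain_error")
  }
  if (any(ns < 2) || any(sds <= 0)) {
    stop_gusnet("each group needs n >= 2 and sd > 0",
                class = "gusnet_domain_error")
  }
  N <- sum(ns)
  grand <- sum(ns * means) / N
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum((ns - 1) * sds^2)
  df1 <- k - 1
  df2 <- N - k
  F <- (ss_between / df1) / (ss_within / df2)
  tibble::tibble(F = F, df1 = df1, df2 = df2,
                 p_value = stats::pf(F, df1, df2, lower.tail = FALSE))
}
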