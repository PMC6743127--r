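test_that("the MDI-experience comparison reproduces the published numbers", {
  res <- prop_diff_ci(n1 = 74, p1 = 0.527, n2 = 29, p2 = 0.138)
  expect_equal(res$delta, 38.9, tolerance = 0.01)
  expect_equal(res$ci_low, 19.6, tolerance = 0.2 / 19.6)
  expect_equal(res$ci_high, 58.2, tolerance = 0.2 / 58.2)
  expect_equal(round(res$p_value, 4), 7e-04)

  # SMI experience: only the difference is recoverable from the printout
  smi <- prop_diff_ci(n1 = 74, p1 = 0.185, n2 = 29, p2 = 0.056)
  expect_equal(smi$delta, 12.9, tolerance = 0.01)
})

test_that("proportion comparisons are antisymmetric with shrinking CIs", {
  a <- prop_diff_ci(n1 = 50, x1 = 30, n2 = 40, x2 = 12)
  b <- prop_diff_ci(n1 = 40, x1 = 12, n2 = 50, x2 = 30)
  expect_equal(a$delta, -b$delta)
  expect_equal(a$ci_low, -b$ci_high)
  expect_equal(a$ci_high, -b$ci_low)

  # equal proportions and sizes: symmetric about zero
  s <- prop_diff_ci(n1 = 30, p1 = 0.4, n2 = 30, p2 = 0.4)
  expect_equal(s$delta, 0)
  expect_equal(s$ci_low, -s$ci_high)

  # CI width non-increasing in each sample size
  widths <- sapply(c(20, 40, 80, 160), function(n) {
    r <- prop_diff_ci(n1 = n, p1 = 0.5, n2 = 30, p2 = 0.3)
    r$ci_high - r$ci_low
  })
  expect_true(all(diff(widths) < 0))

  # extreme proportions: hand evaluation of the formula, upper clipped
  ext <- prop_diff_ci(n1 = 10, p1 = 1, n2 = 10, p2 = 0)
  expect_equal(ext$delta, 100)
  expect_equal(ext$ci_high, 100)
  expect_equal(ext$ci_low, 90)   # 100 - (0 + (1/10 + 1/10)/2) * 100

  expect_error(prop_diff_ci(n1 = 0, p1 = 0.5, n2 = 10, p2 = 0.5),
               class = "gusnet_domain_error")
  expect_error(prop_diff_ci(n1 = 10, p1 = 1.2, n2 = 10, p2 = 0.5),
               class = "gusnet_domain_error")
})

test_that("chi-squared statistics match the direct formula", {
  tab <- rbind(c(39, 35), c(4, 25))
  res <- chi_square_test(tab)
  # independent oracle: sum((O-E)^2 / E) from the marginals
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - E)^2 / E))
  expect_equal(res$statistic, 12.98, tolerance = 0.001)
  expect_equal(res$df, 1)

  ident <- rbind(c(10, 20, 5), c(10, 20, 5))
  res2 <- chi_square_test(ident)
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p_value, 1)
  expect_equal(res2$df, 2)

  tab23 <- rbind(c(12, 7, 21), c(3, 14, 9))
  E23 <- outer(rowSums(tab23), colSums(tab23)) / sum(tab23)
  expect_equal(chi_square_test(tab23)$statistic, sum((tab23 - E23)^2 / E23))

  expect_error(chi_square_test(rbind(c(0, 0), c(3, 4))),
               class = "gusnet_degenerate_table")
  expect_error(chi_square_test(matrix(1:3, ncol = 1)),
               class = "gusnet_domain_error")
})

test_that("summary-statistics ANOVA reproduces the published age comparison", {
  res <- anova_from_summary(means = c(68.6, 69, 67.6),
                            sds = c(12.3, 10.4, 12.4),
                            ns = c(27, 28, 19))
  expect_equal(res$p_value, 0.9234, tolerance = 0.01 / 0.9234)
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 71)
})

test_that("summary ANOVA agrees with classic ANOVA on raw data", {
  withr::with_seed(63, {
    g <- rep(1:3, times = c(15, 20, 12))
    y <- rnorm(length(g), mean = c(10, 12, 11)[g], sd = 3)
  })
  raw <- stats::aov(y ~ factor(g))
  ftab <- summary(raw)[[1]]
  res <- anova_from_summary(means = tapply(y, g, mean),
                            sds = tapply(y, g, sd),
                            ns = as.vector(table(g)))
  expect_equal(res$F, ftab[["F value"]][1], tolerance = 1e-10)
  expect_equal(res$p_value, ftab[["Pr(>F)"]][1], tolerance = 1e-10)

  # equal means: no between-group signal at all
  eq <- anova_from_summary(means = c(5, 5, 5), sds = c(1, 2, 1),
                           ns = c(10, 10, 10))
  expect_equal(eq$F, 0)
  expect_equal(eq$p_value, 1)

  # two groups: F is the square of the pooled-variance t statistic
  m <- c(10.2, 11.7); s <- c(2.1, 2.6); n <- c(14, 18)
  sp2 <- sum((n - 1) * s^2) / (sum(n) - 2)
  tstat <- (m[1] - m[2]) / sqrt(sp2 * (1 / n[1] + 1 / n[2]))
  two <- anova_from_summary(means = m, sds = s, ns = n)
  expect_equal(two$F, tstat^2, tolerance = 1e-12)

  expect_error(anova_from_summary(c(1, 2), c(1, 1), c(5, 5, 5)),
               class = "gusnet_domain_error")
})
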