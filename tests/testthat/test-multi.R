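# Family-wise procedures, chi-squared, ANOVA, whitening, Tukey HSD and the
# grouping layout.

test_that("fwer reproduces the dice arithmetic", {
  expect_equal(fwer(0.05, 5), 0.227, tolerance = 0.005)
  expect_equal(fwer(0.01, 5), 0.049, tolerance = 0.005)
  expect_equal(fwer(0.37, 1), 0.37)
  expect_error(fwer(1.2, 3), "\\[0, 1\\]")
})

test_that("Holm-Bonferroni walks both p-value families correctly", {
  r1 <- holm_bonferroni(table1_pvalues(1))
  expect_true(all(r1$significant))
  r2 <- holm_bonferroni(table1_pvalues(2))
  expect_equal(r2$label[r2$significant], c("B", "D", "F"))
  expect_false(any(r2$significant[r2$label %in% c("C", "E")]))
  # C fails at exactly alpha/2: strict inequality, and E fails by cascade
  expect_equal(r2$threshold[r2$label == "C"], 0.025)
  expect_false(any(holm_bonferroni(rep(1, 4))$significant))
})

test_that("Hochberg step-up is at least as powerful as Holm", {
  r2 <- hochberg_step_up(table1_pvalues(2))
  expect_true(all(r2$significant))  # largest p (0.03) already passes 0.05
  expect_false(any(hochberg_step_up(rep(1, 4))$significant))
  # property: Holm rejections are a subset of Hochberg rejections
  set.seed(19)
  for (k in 1:300) {
    p <- runif(sample(2:8, 1))^sample(1:3, 1)
    h1 <- holm_bonferroni(p)$significant
    h2 <- hochberg_step_up(p)$significant
    expect_true(all(h2[h1]))
  }
})

test_that("chi-squared tests follow the printed forms", {
  expect_equal(chi2_two_methods(c(10, 20, 30), c(10, 20, 30))$chi2, 0)
  # two categories: N * chi2 equals the squared count difference
  r <- chi2_two_methods(c(70, 50), c(50, 70))
  expect_equal(120 * r$chi2, 400)
  expect_equal(r$df, 1)
  # M = 4 against an independently coded oracle
  set.seed(4)
  e <- c(12, 30, 25, 13); f <- c(20, 22, 28, 10)
  oracle <- sum((e - (e + f) / 2)^2 / ((e + f) / 2))
  expect_equal(chi2_two_methods(e, f)$chi2, oracle)
  expect_error(chi2_two_methods(c(1, 2), c(1, 3)), "equal totals")
  # reference-frequency variant
  expect_equal(chi2_vs_expected(c(5, 5, 5), c(5, 5, 5))$chi2, 0)
  expect_equal(chi2_vs_expected(c(8, 2, 5), c(5, 5, 5))$chi2,
               9 / 5 + 9 / 5 + 0)
  expect_error(chi2_vs_expected(c(1, 2), c(0, 3)), "positive")
})

test_that("binary split rule is the two-category chi-squared in disguise", {
  # exhaustive over n <= 200: (dN)^2 > 4N iff chi2 > 4.0 (the rule's
  # rounding of the 3.84 critical value)
  for (n in seq(2, 200, by = 2)) {
    for (k in seq(n / 2, n)) {
      dn2 <- (2 * k - n)^2
      chi2 <- sum((c(k, n - k) - n / 2)^2 / (n / 2))
      expect_equal(n * chi2, dn2)
      expect_identical(dn2 > 4 * n, chi2 > 4)
    }
  }
})

test_that("one-way ANOVA reproduces the three-method example", {
  pm <- table2_matrix()
  a <- anova_oneway(pm)
  ssA <- sum((pm[, "A"] - mean(pm[, "A"]))^2)
  expect_equal(ssA, 0.044, tolerance = 0.03)  # prints as 0.044; exact 0.043
  expect_equal(a$ss_global, 0.0976, tolerance = 0.001)
  expect_equal(a$critical_value, 3.88, tolerance = 0.002)  # 3.8853
  expect_gt(a$F, a$critical_value)
  expect_false(a$equivalent)
  expect_lt(a$p, 0.01)
  # exact decomposition and df additivity
  expect_equal(a$ss_total, a$ss_global + a$ss_local)
  expect_equal(a$df_total, a$df_global + a$df_local)
  # degenerate all-equal matrix
  flat <- anova_oneway(matrix(1, 4, 3))
  expect_true(is.nan(flat$F))
})

test_that("ANOVA decomposition is exact on random matrices", {
  set.seed(8)
  for (k in 1:40) {
    n <- sample(3:6, 1); M <- sample(2:5, 1)
    a <- anova_oneway(matrix(rnorm(n * M), n, M))
    expect_equal(a$ss_total, a$ss_global + a$ss_local)
  }
})

test_that("nested F test agrees with ANOVA and the lm oracle", {
  pm <- table2_matrix()
  a <- anova_oneway(pm)
  f <- f_test_nested(a$ss_total, a$df_total, a$ss_local, a$df_local)
  expect_equal(f$F, a$F)
  expect_equal(f$p, a$p)
  expect_equal(f_test_nested(5, 10, 5, 8)$F, 0)
  # two-parameter vs one-parameter linear fit against stats::anova
  set.seed(12)
  x <- seq(0, 4, length.out = 20)
  y <- 1 + 0.5 * x + rnorm(20, sd = 0.3)
  m0 <- lm(y ~ 1); m1 <- lm(y ~ x)
  ours <- f_test_nested(sum(resid(m0)^2), m0$df.residual,
                        sum(resid(m1)^2), m1$df.residual)
  oracle <- anova(m0, m1)
  expect_equal(ours$F, oracle$F[2])
  expect_equal(ours$p, oracle$`Pr(>F)`[2])
  expect_error(f_test_nested(5, 8, 6, 8), "more residual df")
})

test_that("two-method ANOVA is the squared pooled t", {
  set.seed(14)
  for (k in 1:25) {
    n <- sample(3:9, 1)
    m <- cbind(rnorm(n), rnorm(n, 0.5))
    a <- anova_oneway(m)
    t2 <- two_sample_t(m[, 1], m[, 2])$t^2
    expect_equal(a$F, t2)
  }
  pm <- table2_matrix()[, c("A", "B")]
  expect_equal(anova_oneway(pm)$F,
               two_sample_t(pm[, 1], pm[, 2])$t^2)
  # equal means: both vanish
  m <- cbind(c(1, 2, 3), c(3, 2, 1))
  expect_equal(anova_oneway(m)$F, 0)
})

test_that("adjusted r-squared penalises parameters", {
  expect_equal(adjusted_r2(1, 5, 50), 1)
  expect_equal(adjusted_r2(0.73, 0, 50), 0.73)
  expect_equal(adjusted_r2(0.9, 5, 50), 0.8886, tolerance = 1e-4)
  expect_error(adjusted_r2(0.5, 10, 11), "n - p - 1")
})

test_that("whitening produces identity covariance", {
  # diagonal covariance: W is the reciprocal-root diagonal
  m <- cbind(rnorm(40, sd = 2), rnorm(40, sd = 0.5), rnorm(40, sd = 1))
  w <- whiten(m)
  expect_equal(w$W %*% w$V %*% t(w$W), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(w$W[1, 2], 0, tolerance = 0.2)
  # random correlated draws: defining identity to 1e-10
  set.seed(33)
  V <- crossprod(matrix(rnorm(9), 3)) + diag(3) * 0.1
  pm <- gen_performance_matrix(3, 30, covariance = V, seed = 1)
  w2 <- whiten(pm)
  expect_lt(max(abs(w2$W %*% w2$V %*% t(w2$W) - diag(3))), 1e-10)
  # duplicated method: floored eigenvalue with a warning
  dup <- cbind(a = rnorm(10), b = rnorm(10))
  dup <- cbind(dup, c = dup[, "a"])
  expect_warning(w3 <- whiten(dup), "floor")
  expect_true(any(w3$floored))
  expect_error(whiten(matrix(1, 5, 3)), "zero variance")
})

test_that("correlated chi-squared reduces correctly and is calibrated", {
  means <- c(0.2, 0.5, 0.8)
  r <- correlated_chi2(means, diag(3))
  expect_equal(r$mu, mean(means))
  expect_equal(r$chi2, sum((means - mean(means))^2))
  expect_equal(r$df, 2)
  expect_equal(correlated_chi2(c(0.4, 0.4, 0.4), diag(3))$chi2, 0)
  # V = sigma^2 I with the sample-size factor equals SS_global / sigma^2
  pm <- table2_matrix()
  a <- anova_oneway(pm)
  sigma2 <- 0.07
  cc <- correlated_chi2(colMeans(pm), sigma2 * diag(3), n_systems = nrow(pm))
  expect_equal(cc$chi2, a$ss_global / sigma2)
  expect_error(correlated_chi2(means, matrix(0, 3, 3)), "singular")
})

test_that("Tukey HSD reproduces the three-method worked example", {
  pm <- table2_matrix()
  h <- tukey_hsd(pm)
  # the paper's 5.12/4.94 use the pooled SD rounded to 0.034; exact values
  # are frozen here and checked against the printed ones at rounding slack
  expect_equal(h$pooled_se, 0.034, tolerance = 0.01)
  expect_equal(h$statistic["A", "B"], 5.146, tolerance = 0.001)
  expect_equal(h$statistic["A", "C"], 4.968, tolerance = 0.001)
  expect_equal(h$statistic["B", "C"], 0.18, tolerance = 0.02)
  expect_equal(abs(0.580 - 0.754) / round(h$pooled_se, 3), 5.12,
               tolerance = 0.002)
  expect_equal(h$critical_value, 3.77, tolerance = 0.005)
  expect_true(h$different["A", "B"])
  expect_true(h$different["A", "C"])
  expect_false(h$different["B", "C"])
  # identical methods: all statistics zero
  same <- tukey_hsd(cbind(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_true(all(same$statistic == 0))
  expect_error(tukey_hsd(cbind(a = c(1, 1), b = c(1, 1))), "zero pooled")
  # affine rescaling leaves statistics and verdicts unchanged
  h2 <- tukey_hsd(performance_matrix(unclass(pm) * 7 - 3))
  expect_equal(h2$statistic, h$statistic)
  expect_identical(h2$different, h$different)
})

test_that("studentized range quantile is exposed and correct", {
  expect_equal(studentized_range_quantile(0.95, 3, 12), 3.77,
               tolerance = 0.005)
})

test_that("grouping layout reproduces the narrative depiction", {
  fx <- fig8_fixture()
  gl <- grouping_layout(fx$means, fx$different)
  expect_equal(gl$columns, list("F", c("E", "A", "B"), c("D", "C")))
  edges <- apply(gl$edges, 1, paste, collapse = "-")
  expect_setequal(edges, c("F-E", "B-D"))
  # all equivalent: one column, best to worst
  none <- fx$different & FALSE
  g1 <- grouping_layout(fx$means, none)
  expect_equal(g1$columns, list(c("F", "E", "A", "B", "D", "C")))
  expect_null(g1$edges)
  # all different: singleton columns in mean order
  alld <- !diag(6); dimnames(alld) <- dimnames(fx$different)
  g2 <- grouping_layout(fx$means, alld)
  expect_equal(lengths(g2$columns), rep(1L, 6))
  expect_equal(unlist(g2$columns), c("F", "E", "A", "B", "D", "C"))
  # asymmetric verdicts rejected
  bad <- fx$different; bad["F", "C"] <- FALSE
  expect_error(grouping_layout(fx$means, bad), "symmetric")
})
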