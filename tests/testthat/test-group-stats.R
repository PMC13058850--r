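test_that("one-sample test recovers printed t/p/d conventions", {
  # one-sided upper-tail p for the printed statistics
  expect_equal(pt(0.728, 109, lower.tail = FALSE), 0.234, tolerance = 5e-4)
  x <- c(1.2, 0.8, 1.5, 0.9, 1.1, 1.3)
  ts <- one_sample_test(x)
  ref <- t.test(x, alternative = "greater")
  expect_equal(ts$t, unname(ref$statistic))
  expect_equal(ts$p, ref$p.value)
  expect_equal(ts$d, ts$t / sqrt(6))
  expect_equal(ts$bf10 * ts$bf01, 1)

  # sidedness: p(t) + p(-t) = 1
  ts_neg <- one_sample_test(-x)
  expect_equal(ts$p + ts_neg$p, 1, tolerance = 1e-12)

  expect_error(one_sample_test(rep(2, 5)), "variance")
  expect_error(one_sample_test(1), "at least 2")
})

test_that("Welch test matches pooled t under equal groups and an oracle df", {
  set.seed(8)
  a <- rnorm(12); b <- rnorm(12)
  w <- welch_test(a, b)
  pooled <- t.test(a, b, var.equal = TRUE, alternative = "greater")
  expect_equal(w$t, unname(pooled$statistic), tolerance = 1e-10)

  # Welch-Satterthwaite df on a 6 + 4 toy, computed from first principles
  x <- c(1.1, 2.3, 0.4, 1.8, 2.0, 0.9); y <- c(3.2, 2.8, 4.1, 3.6)
  w2 <- welch_test(x, y)
  v1 <- var(x) / 6; v2 <- var(y) / 4
  df_oracle <- (v1 + v2)^2 / (v1^2 / 5 + v2^2 / 3)
  expect_equal(w2$df, df_oracle, tolerance = 1e-12)
  expect_equal(w2$t, (mean(x) - mean(y)) / sqrt(v1 + v2), tolerance = 1e-12)

  # equal group means -> t = 0, one-sided p = 0.5
  z <- c(1, 2, 3, 4)
  w3 <- welch_test(z, z)
  expect_equal(w3$t, 0)
  expect_equal(w3$p, 0.5)
})

test_that("JZS Bayes factors reproduce printed values and behave lawfully", {
  expect_equal(jzs_bayes_factor(0.728, 110)$bf01, 7.31, tolerance = 0.005)
  expect_equal(jzs_bayes_factor(-0.443, 110)$bf01, 8.60, tolerance = 0.005)
  expect_equal(jzs_bayes_factor(2.383, 110)$bf10, 1.57, tolerance = 0.005)

  # t = 0 favours the null, increasingly so with n (Lindley behaviour)
  expect_lt(jzs_bayes_factor(0, 10)$bf10, 1)
  expect_gt(jzs_bayes_factor(0, 200)$bf01, jzs_bayes_factor(0, 20)$bf01)

  # monotone in |t| at fixed n, symmetric in sign
  ts <- seq(0, 4, by = 0.5)
  bfs <- vapply(ts, function(t) jzs_bayes_factor(t, 30)$bf10, numeric(1))
  expect_true(all(diff(bfs) > 0))
  expect_equal(jzs_bayes_factor(-1.7, 30)$bf10,
               jzs_bayes_factor(1.7, 30)$bf10, tolerance = 1e-9)
})

test_that("JZS integrator agrees with an independent quadrature", {
  # oracle: marginal likelihood ratio via the noncentral-t representation,
  # integrating the Cauchy prior over the standardised effect size
  bf_oracle <- function(t, n, n2 = NULL, r = sqrt(2) / 2) {
    if (is.null(n2)) { neff <- n; nu <- n - 1 }
    else { neff <- n * n2 / (n + n2); nu <- n + n2 - 2 }
    num <- integrate(function(d)
      suppressWarnings(dt(t, nu, ncp = d * sqrt(neff))) *
        dcauchy(d, 0, r), -Inf, Inf, rel.tol = 1e-10)$value
    num / dt(t, nu)
  }
  for (t in c(-2.5, -0.8, 0, 0.728, 1.5, 3)) {
    for (n in c(10, 40, 110)) {
      expect_equal(jzs_bayes_factor(t, n)$bf10, bf_oracle(t, n),
                   tolerance = 1e-3 * max(1, abs(bf_oracle(t, n))))
    }
  }
  expect_equal(jzs_bayes_factor(1.964, 80, 30)$bf10, bf_oracle(1.964, 80, 30),
               tolerance = 1e-3)
})

test_that("Bonferroni families yield the printed corrected thresholds", {
  tests <- data.frame(
    id = c("p_l", "p_r", "c5_l", "c5_r", "c7_l", "c7_r", "solo"),
    family = c("primary", "primary", rep("control", 4), "extra"),
    p = c(0.02, 0.03, 0.001, 0.5, 0.011, 0.013, 0.04))
  out <- bonferroni_families(tests)
  expect_equal(out$alpha_corrected,
               c(0.025, 0.025, rep(0.0125, 4), 0.05))
  expect_equal(out$significant, c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE))
  tests$family[1] <- NA
  expect_error(bonferroni_families(tests), "family")
})

test_that("Pearson correlations carry Fisher-z intervals", {
  x <- c(1.0, 2.1, 2.9, 4.2, 5.1, 5.8)
  y <- c(1.2, 1.9, 3.3, 3.9, 5.3, 5.6)
  out <- pearson_ci(x, y)
  # closed-form oracle
  r <- cor(x, y)
  z <- atanh(r); se <- 1 / sqrt(6 - 3)
  ci <- tanh(z + qnorm(c(0.025, 0.975)) * se)
  expect_equal(out$r, r)
  expect_equal(out$ci, ci, tolerance = 1e-12)

  # degenerate correlations are clipped, not NaN
  perfect <- pearson_ci(1:6, 2 * (1:6) + 1)
  expect_equal(perfect$r, 1)
  expect_true(all(is.finite(perfect$ci)))
  expect_equal(pearson_ci(1:6, -(1:6))$r, -1)
  expect_error(pearson_ci(1:3, 1:3), "at least 4")
  expect_error(pearson_ci(rep(1, 6), 1:6), "variance")
})

test_that("one-sample test maintains its nominal type-I error rate", {
  set.seed(314)
  p <- replicate(10000, one_sample_test(rnorm(15))$p)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.01)
})
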