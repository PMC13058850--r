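#' One-sample t-test with effect size and JZS Bayes factor
#'
#' Frequentist test one-sided by default (alternative: mean greater than
#' `null_value`, the convention for directional grid-signal hypotheses);
#' the accompanying JZS Bayes factor is two-sided (Cauchy prior on the
#' standardised effect). Cohen's d is `t / sqrt(n)`.
#'
#' @param values sample.
#' @param null_value null mean.
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @param prior_width Cauchy prior scale r for the Bayes factor.
#' @return object of class `test_result`: `t`, `df`, `p`, `d`, `n`,
#'   `bf10`, `bf01`, `alternative`.
#' @export
one_sample_test <- function(values, null_value = 0, alternative = "greater",
                            prior_width = sqrt(2) / 2) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2L) stop("need at least 2 finite values")
  if (stats::sd(values) == 0)
    stop("zero variance: t statistic undefined")
  ht <- stats::t.test(values, mu = null_value, alternative = alternative)
  t <- unname(ht$statistic)
  bf <- jzs_bayes_factor(t, n, r = prior_width)
  structure(list(t = t, df = unname(ht$parameter), p = ht$p.value,
                 d = t / sqrt(n), n = n, bf10 = bf$bf10, bf01 = bf$bf01,
                 alternative = alternative, test = "one-sample"),
            class = "test_result")
}

#' Welch two-sample t-test with effect size and JZS Bayes factor
#'
#' Welch statistic and Welch-Satterthwaite degrees of freedom; one-sided by
#' default (alternative: mean of `groupA` greater). Cohen's d uses the
#' pooled standard deviation. The Bayes factor uses the pooled-variance t
#' and effective sample size `n1*n2/(n1+n2)` (the standard two-sample JZS
#' formula), even though the frequentist test is Welch — a deliberate,
#' documented mismatch mirroring common tooling.
#'
#' @param groupA,groupB samples.
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @param prior_width Cauchy prior scale r.
#' @return `test_result` with `t`, `df` (fractional), `p`, `d`, `n1`, `n2`,
#'   `bf10`, `bf01`.
#' @export
welch_test <- function(groupA, groupB, alternative = "greater",
                       prior_width = sqrt(2) / 2) {
  groupA <- groupA[is.finite(groupA)]; groupB <- groupB[is.finite(groupB)]
  n1 <- length(groupA); n2 <- length(groupB)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 finite values")
  if (stats::sd(groupA) == 0 && stats::sd(groupB) == 0)
    stop("zero variance in both groups")
  ht <- stats::t.test(groupA, groupB, var.equal = FALSE,
                      alternative = alternative)
  sp <- sqrt(((n1 - 1) * stats::var(groupA) + (n2 - 1) * stats::var(groupB)) /
               (n1 + n2 - 2))
  d <- (mean(groupA) - mean(groupB)) / sp
  t_pooled <- d / sqrt(1 / n1 + 1 / n2)
  bf <- jzs_bayes_factor(t_pooled, n1, n2, r = prior_width)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, d = d, n1 = n1, n2 = n2,
                 bf10 = bf$bf10, bf01 = bf$bf01,
                 alternative = alternative, test = "welch"),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: t(%.4g) = %.3f, p = %.4g, d = %.3f, bf10 = %.3g, bf01 = %.3g\n",
              x$test, x$df, x$t, x$p, x$d, x$bf10, x$bf01))
  invisible(x)
}

#' JZS (Jeffreys-Zellner-Siow) Bayes factor for a t statistic
#'
#' Default two-sided Bayesian t-test: a Cauchy prior of scale `r` on the
#' standardised effect size against a point null, integrated numerically
#' (Rouder's one-sample formula; the two-sample case uses the pooled t with
#' effective sample size `n1*n2/(n1+n2)` and `n1+n2-2` degrees of freedom).
#'
#' @param t observed t statistic.
#' @param n sample size (one-sample), or first group size.
#' @param n2 optional second group size (two-sample).
#' @param r Cauchy prior scale (default 0.707 = sqrt(2)/2).
#' @param rel_tol relative integration tolerance.
#' @return list with `bf10` (evidence for the alternative) and
#'   `bf01 = 1/bf10`.
#' @export
#' @examples
#' jzs_bayes_factor(0.728, 110)$bf01   # about 7.31
jzs_bayes_factor <- function(t, n, n2 = NULL, r = sqrt(2) / 2, rel_tol = 1e-8) {
  stopifnot(is.finite(t), n >= 2)
  if (is.null(n2)) {
    neff <- n; nu <- n - 1
  } else {
    stopifnot(n2 >= 2)
    neff <- n * n2 / (n + n2); nu <- n + n2 - 2
  }
  # marginal likelihood under the alternative: integrate over the prior on
  # the variance scale g (inverse-gamma(1/2, r^2/2) equivalent form)
  integrand <- function(g) {
    (1 + neff * g * r^2)^(-1 / 2) *
      (1 + t^2 / ((1 + neff * g * r^2) * nu))^(-(nu + 1) / 2) *
      (2 * pi)^(-1 / 2) * g^(-3 / 2) * exp(-1 / (2 * g))
  }
  num <- tryCatch(
    stats::integrate(integrand, 0, Inf, rel.tol = rel_tol,
                     subdivisions = 500L),
    error = function(e) stop("JZS integration failed: ", conditionMessage(e)))
  if (num$message != "OK")
    stop("JZS integration did not converge: ", num$message)
  bf10 <- num$value / (1 + t^2 / nu)^(-(nu + 1) / 2)
  list(bf10 = bf10, bf01 = 1 / bf10)
}

#' Bonferroni correction by test family
#'
#' Each family of m tests is tested at `alpha / m` (e.g. the primary
#' 6-fold hypothesis in two hemispheres at 0.025; the 5-/7-fold controls in
#' two hemispheres at 0.0125).
#'
#' @param tests data frame with at least columns `id`, `family`, `p`.
#' @param alpha family-wise error rate before division.
#' @return `tests` with `alpha_corrected` and logical `significant` added.
#' @export
bonferroni_families <- function(tests, alpha = 0.05) {
  stopifnot(all(c("id", "family", "p") %in% names(tests)))
  if (any(is.na(tests$family)))
    stop("every test must be assigned a family")
  size <- table(tests$family)
  tests$alpha_corrected <- alpha / as.numeric(size[as.character(tests$family)])
  tests$significant <- tests$p < tests$alpha_corrected
  tests
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y paired samples, n >= 4.
#' @param confidence confidence level.
#' @return list with `r`, `ci` (length 2, clipped to `[-1, 1]`), `n`,
#'   `p` (two-sided).
#' @export
pearson_ci <- function(x, y, confidence = 0.95) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    ci <- c(r, r)
    p <- 0
  } else {
    z <- atanh(r)
    se <- 1 / sqrt(n - 3)
    q <- stats::qnorm(1 - (1 - confidence) / 2)
    ci <- pmin(pmax(tanh(c(z - q * se, z + q * se)), -1), 1)
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
  }
  list(r = r, ci = ci, n = n, p = p, confidence = confidence)
}
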