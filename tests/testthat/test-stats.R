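test_that("rank-sum test matches the worked small-sample cases", {
  # symmetric case: statistic at its null expectation, p = 1
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$p_value, 1)
  # fully separated minimal case: exact p = 2/6
  r2 <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(r2$p_value, 1 / 3)
  expect_equal(unname(r2$n_per_group), c(2L, 2L))
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-missing")
})

test_that("exact rank-sum p equals the enumeration oracle (n <= 8)", {
  set.seed(99)
  for (m in c(2, 3, 5, 8)) {
    for (n in c(2, 4, 6, 8)) {
      x <- rnorm(m); y <- rnorm(n, 0.8)
      expect_equal(wilcoxon_rank_sum(x, y)$p_value,
                   enumerated_ranksum_p(x, y),
                   info = sprintf("m=%d n=%d", m, n))
    }
  }
})

test_that("rank tests are invariant to monotone relabeling and label swap", {
  set.seed(7)
  x <- rnorm(12); y <- rnorm(15, 0.5)
  p <- wilcoxon_rank_sum(x, y)$p_value
  expect_equal(wilcoxon_rank_sum(y, x)$p_value, p)
  expect_equal(wilcoxon_rank_sum(exp(x), exp(y))$p_value, p)
  g <- list(rnorm(8), rnorm(8), rnorm(8))
  expect_equal(kruskal_wallis(lapply(g, exp))$p_value,
               kruskal_wallis(g)$p_value)
})

test_that("Kruskal-Wallis matches the hand-computed statistic", {
  # groups {1,2},{3,4},{5,6}: H = 179/7 - 21
  r <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(unname(r$statistic), 179 / 7 - 21)
  expect_equal(r$p_value, pchisq(179 / 7 - 21, 2, lower.tail = FALSE))
  # identical groups: statistic 0, p = 1
  same <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  r2 <- kruskal_wallis(same)
  expect_equal(unname(r2$statistic), 0)
  expect_equal(r2$p_value, 1)
  expect_error(kruskal_wallis(list(1:3, 4:6)), "wilcoxon_rank_sum")
})

test_that("mean-difference tests match closed forms", {
  # all-zero deltas: t = 0, p = 1
  r <- mean_difference_test(deltas = c(0, 0, 0))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # one-sample t closed form: t = mean / (sd / sqrt(n))
  d <- c(-1, -2, -3)
  r2 <- mean_difference_test(deltas = d)
  expect_equal(unname(r2$statistic), mean(d) / (sd(d) / sqrt(3)))
  expect_equal(r2$p_value, 2 * pt(abs(mean(d) / (sd(d) / sqrt(3))), 2,
                                  lower.tail = FALSE))
  # ANOVA on identical groups: F = 0
  r3 <- mean_difference_test(groups = list(c(1, 2), c(1, 2), c(1, 2)))
  expect_equal(unname(r3$statistic), 0)
  # zero-variance input: NA p with warning, not an error
  expect_warning(r4 <- mean_difference_test(deltas = c(2, 2, 2)),
                 "zero variance")
  expect_true(is.na(r4$p_value))
})

test_that("Pearson correlation matches the direct covariance formula", {
  expect_equal(pearson_correlation(1:5, 2 * (1:5) + 1)$r, 1)
  expect_equal(pearson_correlation(1:5, -(1:5))$r, -1)
  x <- c(1, 2, 3, 4); y <- c(2, 2, 5, 4)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  res <- pearson_correlation(x, y)
  expect_equal(res$r, r_direct)
  expect_equal(res$r2, r_direct^2)
  expect_equal(pearson_correlation(c(1, 1, 1), 1:3)$note, "zero variance")
  expect_error(pearson_correlation(1:2, 1:2), "3 complete pairs")
})

test_that("Kaplan-Meier estimate matches the product-limit definition", {
  # 10 uncensored times 1..10: S steps by 0.1, median 5
  fit <- km_fit(1:10, rep(1, 10))
  sf <- fit$survfit
  expect_equal(sf$surv, seq(0.9, 0, by = -0.1))
  expect_equal(unname(fit$medians), 5)
  # against the definition-based oracle with censoring
  times <- c(1, 2, 2, 3, 5, 6, 6, 8, 11, 12)
  events <- c(1, 1, 0, 1, 0, 1, 1, 0, 1, 0)
  pl <- product_limit(times, events)
  fit2 <- km_fit(times, events)
  expect_equal(fit2$survfit$surv[fit2$survfit$n.event > 0], pl$surv)
  # identical survival in both groups: log-rank statistic 0
  fit3 <- km_fit(rep(1:5, 2), rep(1, 10), rep(c("a", "b"), each = 5))
  expect_equal(fit3$logrank_chi2, 0, tolerance = 1e-10)
  # all-censored group: median not reached
  fit4 <- km_fit(c(1:5, 1:5), c(rep(1, 5), rep(0, 5)),
                 rep(c("a", "b"), each = 5))
  expect_true(is.na(fit4$medians[["b"]]))
})

test_that("log-rank detects a simulated hazard difference", {
  withr::with_seed(11, {
    t1 <- rexp(500, 1)
    t2 <- rexp(500, exp(0.7))
    fit <- km_fit(c(t1, t2), rep(1, 1000), rep(c("a", "b"), each = 500))
    expect_lt(fit$logrank_p, 1e-6)
    expect_gt(fit$medians[["a"]], fit$medians[["b"]])
  })
})

test_that("Cox fit maximizes the partial likelihood", {
  # 3 subjects, 2 events, binary covariate: compare with the directly
  # maximized log partial likelihood
  times <- c(1, 2, 3); events <- c(1, 1, 0); x <- c(1, 0, 1)
  fit <- cox_fit(times, events, data.frame(x = x))
  beta_oracle <- optimize(function(b) -cox_logpl(b, times, events, x),
                          c(-5, 5))$minimum
  expect_equal(fit$coef$coef, beta_oracle, tolerance = 1e-4)
  # duplicating the data leaves the point estimate and narrows the CI;
  # exact under Breslow tie handling (duplication creates ties, and the
  # Efron correction deliberately treats tied events differently)
  fit_b <- cox_fit(times, events, data.frame(x = x), ties = "breslow")
  fit2 <- cox_fit(rep(times, 2), rep(events, 2),
                  data.frame(x = rep(x, 2)), ties = "breslow")
  expect_equal(fit2$coef$coef, fit_b$coef$coef, tolerance = 1e-6)
  expect_lt(fit2$coef$ci_high - fit2$coef$ci_low,
            fit_b$coef$ci_high - fit_b$coef$ci_low)
})

test_that("Cox recovery: null covariate gives HR near 1 at n = 500", {
  withr::with_seed(13, {
    x <- rbinom(500, 1, 0.5)
    t <- rexp(500, 0.02)
    fit <- cox_fit(t, rep(1, 500), data.frame(x = x))
    se <- (log(fit$coef$ci_high) - log(fit$coef$ci_low)) / (2 * 1.959964)
    # 3-SE band: a ~99.7% interval for a single fixed-seed draw
    expect_lt(abs(fit$coef$coef), 3 * se)
    expect_true(fit$coef$ci_low < fit$coef$hr &&
                  fit$coef$hr < fit$coef$ci_high)
  })
})

test_that("monotone likelihood is flagged as non-convergence", {
  fit <- cox_fit(c(1, 2), c(1, 0), data.frame(x = c(1, 0)))
  expect_false(fit$converged)
})

test_that("logistic regression matches 2x2 closed forms", {
  tab_to_data <- function(a, b, c_, d) {
    data.frame(y = c(rep(1, a), rep(0, b), rep(1, c_), rep(0, d)),
               x = c(rep(1, a + b), rep(0, c_ + d)))
  }
  d1 <- tab_to_data(10, 10, 10, 10)
  f1 <- logistic_fit(d1$y, data.frame(x = d1$x))
  expect_equal(f1$coef$or[f1$coef$term == "x"], 1)
  d2 <- tab_to_data(20, 10, 10, 20)
  f2 <- logistic_fit(d2$y, data.frame(x = d2$x))
  expect_equal(f2$coef$or[f2$coef$term == "x"], 4, tolerance = 1e-6)
  # separation flag
  d3 <- data.frame(y = c(0, 0, 0, 1, 1, 1), x = c(0, 0, 0, 1, 1, 1))
  f3 <- logistic_fit(d3$y, data.frame(x = d3$x))
  expect_false(f3$converged)
  expect_error(logistic_fit(rep(1, 10), data.frame(x = rnorm(10))),
               "both outcome classes")
})

test_that("logistic recovery: null and non-null effects within 2 SE", {
  withr::with_seed(17, {
    x <- rnorm(500)
    y0 <- rbinom(500, 1, 0.5)
    f0 <- logistic_fit(y0, data.frame(x = x))
    se0 <- (log(f0$coef$ci_high) - log(f0$coef$ci_low))[2] / (2 * 1.959964)
    expect_lt(abs(f0$coef$coef[2]), 2 * se0)
    y1 <- rbinom(500, 1, plogis(-0.2 + 0.8 * x))
    f1 <- logistic_fit(y1, data.frame(x = x))
    se1 <- (log(f1$coef$ci_high) - log(f1$coef$ci_low))[2] / (2 * 1.959964)
    expect_lt(abs(f1$coef$coef[2] - 0.8), 2 * se1)
  })
})
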