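test_that("simple regression recovers exact fits and its identities", {
  x <- 1:20
  r <- suppressWarnings(simple_regression(x, 2 * x + 1))  # perfect fit
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 1)
  expect_equal(r$r_squared, 1)
  set.seed(1)
  xn <- rnorm(56); yn <- 0.5 * xn + rnorm(56)
  rn <- simple_regression(xn, yn)
  expect_equal(rn$r_squared, cor(xn, yn)^2, tolerance = 1e-10)
  sse <- sum(residuals(rn$lm_fit)^2)
  sst <- sum((yn - mean(yn))^2)
  expect_equal(rn$r_squared, 1 - sse / sst, tolerance = 1e-10)
  # band widens away from the predictor mean
  w <- rn$band$upr - rn$band$lwr
  expect_lt(w[which.min(abs(rn$band$x - mean(xn)))], w[1])
  expect_lt(w[which.min(abs(rn$band$x - mean(xn)))], w[length(w)])
  expect_error(simple_regression(rep(1, 10), rnorm(10)),
               class = "octspeckle_degenerate_predictor")
  expect_error(simple_regression(1:3, 1:4),
               class = "octspeckle_domain_error")
})

test_that("regression p-values are uniform under the null", {
  set.seed(8)
  rej <- mean(replicate(1000,
    simple_regression(rnorm(56), rnorm(56))$p_value < 0.05))
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("forward stepwise picks exact signals and obeys its thresholds", {
  set.seed(2)
  x1 <- rnorm(50); x2 <- rnorm(50); x3 <- rnorm(50)
  sw <- forward_stepwise(list(x1 = x1, x2 = x2, x3 = x3), y = 2 * x1)
  expect_identical(sw$predictors, "x1")
  expect_equal(unname(coef(sw)["x1"]), 2, tolerance = 1e-8)
  # alpha_enter = 1 admits every useful orthogonal predictor
  y <- x1 + x2 + x3 + rnorm(50, 0, 0.1)
  sw_all <- forward_stepwise(list(x1 = x1, x2 = x2, x3 = x3), y,
                             alpha_enter = 1)
  expect_setequal(sw_all$predictors, c("x1", "x2", "x3"))
  # alpha_enter -> 0 admits none
  sw_none <- forward_stepwise(list(x1 = x1, x2 = x2, x3 = x3), y,
                              alpha_enter = 1e-300)
  expect_length(sw_none$predictors, 0)
  # every entry p-value is below the threshold; refit reproduces stored fit
  expect_true(all(sw_all$steps$p_value < 1))
  refit <- lm(y ~ x1 + x2 + x3)
  expect_equal(sort(coef(sw_all)), sort(coef(refit)), tolerance = 1e-10)
  # collinear candidates are skipped with a warning
  expect_warning(
    forward_stepwise(list(x1 = x1, x1b = x1 * 2), y = 3 * x1 + rnorm(50)),
    class = "octspeckle_warning")
  expect_error(forward_stepwise(list(a = rnorm(5)), rnorm(4)),
               class = "octspeckle_domain_error")
})

test_that("stepwise recovers the generating IOP model from a large cohort", {
  coh <- simulate_cohort(cohort_spec(n_subjects = 5000, seed = 4))
  sw <- suppressWarnings(
    forward_stepwise(as.list(coh[cohort_candidates]), coh$IOP_nc))
  expect_identical(sw$predictors[1:2], c("CCT", "GG_a"))
  expect_lt(abs(coef(sw)["CCT"] / 0.0248 - 1), 0.05)
  expect_lt(abs(coef(sw)["GG_a"] / -16.534 - 1), 0.05)
})

test_that("sample-size formula matches t-quantiles and scales correctly", {
  n <- sample_size(sigma = 1, delta_mu = 1, alpha = 0.05, beta = 0.01,
                   N = 56)
  expect_equal(n, (qt(0.95, 54) + qt(0.99, 54))^2, tolerance = 1e-12)
  expect_equal(n, 16.6, tolerance = 0.01)
  expect_identical(sample_size(1, 1, N = 56, ceiling = TRUE), 17)
  # homogeneity: n scales as sigma^2 and 1/delta_mu^2
  expect_equal(sample_size(2, 1, N = 56), 4 * n)
  expect_equal(sample_size(1, 2, N = 56), n / 4)
  dmu <- seq(0.5, 3, by = 0.5)
  ns <- vapply(dmu, function(d) sample_size(1, d, N = 56), 0)
  expect_true(all(diff(ns) < 0))
  expect_error(sample_size(1, 0), class = "octspeckle_domain_error")
})

test_that("median split: arithmetic, tie handling, degenerate input", {
  df <- data.frame(IOP_nc = c(1, 2, 3, 4))
  sp <- median_split(df, "IOP_nc")
  expect_equal(sp$median, 2.5)
  expect_equal(sp$below$IOP_nc, c(1, 2))
  expect_equal(sp$above$IOP_nc, c(3, 4))
  # values equal to the median go to the lower group, counted
  sp2 <- median_split(data.frame(IOP_nc = c(1, 2, 2, 5, 9)), "IOP_nc")
  expect_equal(sp2$median, 2)
  expect_identical(sp2$n_ties, 2L)
  expect_equal(nrow(sp2$below), 3L)
  expect_warning(median_split(data.frame(IOP_nc = rep(4, 6)), "IOP_nc"),
                 class = "octspeckle_warning")
  expect_error(median_split(df[0, , drop = FALSE], "IOP_nc"),
               class = "octspeckle_insufficient_sample")
  # group imbalance is controlled by the median ties: with k records tied
  # at the median, |#below - #above| = |#(<med) + k - #(>med)| <= 2k - 1
  # (and 0 when k = 0, the even-n untied case)
  set.seed(12)
  for (i in 1:20) {
    d <- data.frame(v = sample(1:10, 25, replace = TRUE))
    s <- suppressWarnings(median_split(d, "v"))
    expect_lte(abs(nrow(s$below) - nrow(s$above)),
               max(2L * s$n_ties - 1L, 0L))
  }
})

test_that("group comparison: null p-value and power against shifted normals", {
  g <- data.frame(x = rnorm(20))
  same <- group_compare(g, g, "x")
  expect_equal(same$p_value, 1, tolerance = 0.01)
  expect_equal(same$mean1, same$mean2)
  expect_error(group_compare(g, g[1, , drop = FALSE], "x"),
               class = "octspeckle_insufficient_sample")
  # analytic normal-approximation power of the rank-sum test at
  # delta = 1 SD, n = 28 vs 28 (exact moments under the alternative)
  d <- 1; n1 <- 28; n2 <- 28
  p1 <- pnorm(d / sqrt(2))
  p2 <- integrate(function(x) dnorm(x) * (1 - pnorm(x - d))^2,
                  -Inf, Inf)$value
  p3 <- integrate(function(y) dnorm(y, mean = d) * pnorm(y)^2,
                  -Inf, Inf)$value
  mu1 <- n1 * n2 * p1
  v1 <- n1 * n2 * p1 * (1 - p1) + n1 * n2 * (n1 - 1) * (p2 - p1^2) +
    n1 * n2 * (n2 - 1) * (p3 - p1^2)
  mu0 <- n1 * n2 / 2
  v0 <- n1 * n2 * (n1 + n2 + 1) / 12
  crit <- qnorm(0.975) * sqrt(v0)
  pow <- pnorm((mu0 - crit - mu1) / sqrt(v1)) +
    1 - pnorm((mu0 + crit - mu1) / sqrt(v1))
  set.seed(3)
  rej <- mean(replicate(1000, {
    group_compare(data.frame(x = rnorm(28)),
                  data.frame(x = rnorm(28, mean = d)), "x")$p_value < 0.05
  }))
  # 3 SE Monte-Carlo slack plus 0.035 for the skewness of the rank-sum
  # statistic under the alternative, which the normal approximation ignores
  expect_lt(abs(rej - pow), 3 * sqrt(pow * (1 - pow) / 1000) + 0.035)
})

test_that("GG density contrast matches a brute-force two-sample KS", {
  g1 <- c(a = 0.30, v = 0.43, p = 2.85)
  g2 <- c(a = 0.28, v = 0.44, p = 2.77)
  cp <- compare_group_pdfs(g1, g2, m = 28)
  s1 <- cp$pseudo_sample1; s2 <- cp$pseudo_sample2
  D_oracle <- max(vapply(c(s1, s2), function(t)
    abs(mean(s1 <= t) - mean(s2 <= t)), 0))
  expect_equal(cp$statistic, D_oracle, tolerance = 1e-12)
  # identical parameter sets: D = 0, p ~ 1
  same <- compare_group_pdfs(g1, g1)
  expect_lte(same$statistic, 1 / same$m)
  expect_gt(same$p_value, 0.99)
  # widely separated scales: essentially disjoint support mass
  far <- compare_group_pdfs(c(a = 0.1, v = 0.43, p = 2.8),
                            c(a = 10, v = 0.43, p = 2.8))
  expect_lt(far$p_value, 1e-6)
  expect_error(compare_group_pdfs(c(a = -1, v = 1, p = 1), g1),
               class = "octspeckle_domain_error")
})
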