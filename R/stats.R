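#' Simple linear regression with coefficient of determination and 95%
#' confidence band
#'
#' Ordinary least squares of `y` on a single predictor `x`, reporting the
#' slope, intercept, \eqn{R^2}, the F-test p-value of the slope and a 95%
#' pointwise confidence band for the mean response over the predictor
#' range — the quantities plotted in the study's regression figures.
#'
#' @param x predictor vector (non-constant).
#' @param y response vector of the same length.
#' @param band_points number of grid points for the confidence band.
#' @param conf_level confidence level of the band (default 0.95).
#' @return an object of class `"simple_regression"`: list with `slope`,
#'   `intercept`, `r_squared`, `p_value`, `n`, `band` (data frame `x`,
#'   `fit`, `lwr`, `upr`) and the underlying `lm` fit.
#' @examples
#' r <- simple_regression(1:10, 2 * (1:10) + 1)
#' r$slope; r$r_squared
#' @export
simple_regression <- function(x, y, band_points = 100,
                              conf_level = 0.95) {
  if (length(x) != length(y))
    oct_error("`x` and `y` must have equal length",
              "octspeckle_domain_error")
  keep <- stats::complete.cases(x, y)
  x <- as.numeric(x[keep]); y <- as.numeric(y[keep])
  if (length(x) < 3L)
    oct_error("need at least 3 complete observations",
              "octspeckle_insufficient_sample")
  if (stats::sd(x) == 0)
    oct_error("predictor is constant; regression is degenerate",
              "octspeckle_degenerate_predictor")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p_value <- unname(stats::pf(fstat[1L], fstat[2L], fstat[3L],
                              lower.tail = FALSE))
  grid <- seq(min(x), max(x), length.out = band_points)
  pred <- stats::predict(fit, newdata = data.frame(x = grid),
                         interval = "confidence", level = conf_level)
  structure(list(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r_squared = sm$r.squared,
    p_value = p_value,
    n = length(x),
    band = data.frame(x = grid, fit = pred[, "fit"], lwr = pred[, "lwr"],
                      upr = pred[, "upr"]),
    lm_fit = fit), class = "simple_regression")
}

#' @export
print.simple_regression <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Simple regression (n = %d): y = %s + %s x,  R^2 = %s,  p = %s\n",
    x$n, format(x$intercept, digits = digits),
    format(x$slope, digits = digits),
    format(x$r_squared, digits = digits),
    format.pval(x$p_value, digits = digits)))
  invisible(x)
}

#' @export
plot.simple_regression <- function(x, xlab = "x", ylab = "y", ...) {
  d <- x$lm_fit$model
  graphics::plot(d$x, d$y, pch = 19, col = "grey30", xlab = xlab,
                 ylab = ylab, ...)
  graphics::lines(x$band$x, x$band$fit, col = "red", lwd = 2)
  graphics::lines(x$band$x, x$band$lwr, col = "blue", lty = 2)
  graphics::lines(x$band$x, x$band$upr, col = "blue", lty = 2)
  invisible(x)
}

#' Forward stepwise linear regression by partial F-tests
#'
#' Starts with no predictors and, at each step, fits every one-variable
#' addition, selecting the candidate with the smallest partial-F p-value
#' provided it falls below `alpha_enter`; the procedure stops when no
#' remaining candidate qualifies. Ties are broken by larger resulting
#' \eqn{R^2}, then by candidate name order. Candidates whose addition is
#' collinear with the current model are skipped with a warning.
#'
#' @param candidates named list or data frame of candidate predictor
#'   vectors.
#' @param y response vector.
#' @param alpha_enter entry threshold for the partial-F p-value
#'   (default 0.05).
#' @return an object of class `"stepwise_model"`: `predictors` (entry
#'   order), `coefficients` (final refit, intercept first), `r_squared`,
#'   `steps` (data frame of entry p-values and cumulative R^2) and the
#'   final `lm` fit (`NULL` when nothing entered).
#' @examples
#' set.seed(1)
#' x1 <- rnorm(50); x2 <- rnorm(50)
#' forward_stepwise(list(x1 = x1, x2 = x2), y = 2 * x1 + rnorm(50, 0, .1))
#' @export
forward_stepwise <- function(candidates, y, alpha_enter = 0.05) {
  if (is.data.frame(candidates)) candidates <- as.list(candidates)
  if (!length(candidates) || is.null(names(candidates)) ||
      any(!nzchar(names(candidates))))
    oct_error("`candidates` must be a non-empty named list",
              "octspeckle_domain_error")
  n <- length(y)
  if (any(vapply(candidates, length, 0L) != n))
    oct_error("all candidates must have the length of `y`",
              "octspeckle_domain_error")
  if (n <= length(candidates) + 1L)
    oct_error("need more observations than candidate predictors",
              "octspeckle_insufficient_sample")
  dat <- data.frame(.y = as.numeric(y), candidates, check.names = FALSE)

  selected <- character(0L)
  steps <- data.frame(variable = character(0L), p_value = numeric(0L),
                      r_squared = numeric(0L), stringsAsFactors = FALSE)
  repeat {
    remaining <- setdiff(names(candidates), selected)
    if (!length(remaining)) break
    trial <- lapply(remaining, function(v) {
      fml <- stats::reformulate(c(selected, v), response = ".y")
      fit <- suppressWarnings(stats::lm(fml, data = dat))
      if (anyNA(stats::coef(fit))) {
        oct_warn(sprintf(
          "candidate '%s' is collinear with the current model; skipped", v))
        return(NULL)
      }
      sm <- suppressWarnings(summary(fit))
      p <- sm$coefficients[v, "Pr(>|t|)"]
      list(v = v, p = if (is.finite(p)) p else 1, r2 = sm$r.squared)
    })
    trial <- Filter(Negate(is.null), trial)
    if (!length(trial)) break
    pv <- vapply(trial, `[[`, 0, "p")
    r2 <- vapply(trial, `[[`, 0, "r2")
    nm <- vapply(trial, `[[`, "", "v")
    ord <- order(pv, -r2, nm)
    best <- trial[[ord[1L]]]
    if (best$p >= alpha_enter) break
    selected <- c(selected, best$v)
    steps <- rbind(steps, data.frame(variable = best$v, p_value = best$p,
                                     r_squared = best$r2,
                                     stringsAsFactors = FALSE))
    if (best$r2 >= 1 - 1e-12) break  # perfect fit: nothing left to explain
  }
  final <- if (length(selected))
    suppressWarnings(
      stats::lm(stats::reformulate(selected, response = ".y"), data = dat))
  else NULL
  structure(list(
    predictors = selected,
    coefficients = if (!is.null(final)) stats::coef(final)
                   else c(`(Intercept)` = mean(dat$.y)),
    r_squared = if (!is.null(final))
      suppressWarnings(summary(final)$r.squared) else 0,
    steps = steps, alpha_enter = alpha_enter, n = n,
    lm_fit = final), class = "stepwise_model")
}

#' @export
print.stepwise_model <- function(x, digits = 4, ...) {
  if (!length(x$predictors)) {
    cat("Forward stepwise regression: no predictor entered the model\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Forward stepwise regression (n = %d, alpha_enter = %g)\n", x$n,
    x$alpha_enter))
  cat("  entered:", paste(x$predictors, collapse = ", "), "\n")
  cat("  coefficients:\n")
  print(round(x$coefficients, digits))
  cat(sprintf("  R^2 = %s\n", format(x$r_squared, digits = digits)))
  invisible(x)
}

#' @export
coef.stepwise_model <- function(object, ...) object$coefficients

#' @export
predict.stepwise_model <- function(object, newdata, ...) {
  if (is.null(object$lm_fit))
    return(rep.int(unname(object$coefficients[1L]),
                   if (missing(newdata)) object$n else nrow(newdata)))
  if (missing(newdata)) stats::predict(object$lm_fit, ...)
  else stats::predict(object$lm_fit, newdata = newdata, ...)
}

#' Sample size for detecting a mean change
#'
#' Power-based sample size for detecting a change `delta_mu` in the mean of
#' a parameter with standard deviation `sigma`:
#' \deqn{n = \frac{\sigma^2 \left(t_{1-\alpha,\,N-2} +
#'   t_{1-\beta,\,N-2}\right)^2}{(\Delta\mu)^2}}
#' with one-sided Student-t quantiles on `N - 2` degrees of freedom taken
#' from a reference sample of size `N`.
#'
#' @param sigma standard deviation of the parameter (> 0).
#' @param delta_mu detectable mean change, same units (> 0).
#' @param alpha significance level (default 0.05).
#' @param beta type-II error, i.e. 1 - power (default 0.01).
#' @param N reference sample size for the degrees of freedom (>= 3).
#' @param ceiling if `TRUE`, round the result up to the next integer.
#' @return required sample size (real, or integer when `ceiling = TRUE`).
#' @examples
#' sample_size(sigma = 1, delta_mu = 1, alpha = 0.05, beta = 0.01, N = 56)
#' @export
sample_size <- function(sigma, delta_mu, alpha = 0.05, beta = 0.01,
                        N = 56, ceiling = FALSE) {
  check_positive(sigma, "sigma")
  if (!is.numeric(delta_mu) || length(delta_mu) != 1L || delta_mu <= 0)
    oct_error("`delta_mu` must be a single positive number",
              "octspeckle_domain_error")
  if (alpha <= 0 || alpha >= 1 || beta <= 0 || beta >= 1)
    oct_error("`alpha` and `beta` must lie in (0, 1)",
              "octspeckle_domain_error")
  N <- check_count(N, "N", min = 3L)
  tq <- stats::qt(1 - alpha, N - 2) + stats::qt(1 - beta, N - 2)
  n <- sigma^2 * tq^2 / delta_mu^2
  if (ceiling) base::ceiling(n) else n
}

#' Split cohort records at the median of a variable
#'
#' The median is computed over all records (for even counts, the mean of
#' the two middle values). Records strictly below the median form the first
#' group, records strictly above the second; records exactly equal to the
#' median are assigned to the first ("below") group and their count is
#' reported.
#'
#' @param records a data frame of cohort records.
#' @param key name of the split variable (e.g. `"IOP_nc"`).
#' @return an object of class `"median_split"`: list with `below`, `above`
#'   (data frames), `median`, `key` and `n_ties`.
#' @examples
#' df <- data.frame(IOP_nc = c(14, 15, 16, 17))
#' median_split(df, "IOP_nc")$median  # 15.5
#' @export
median_split <- function(records, key) {
  if (!is.data.frame(records) || !key %in% names(records))
    oct_error(sprintf("`records` must be a data frame with column '%s'",
                      key), "octspeckle_schema_error")
  if (nrow(records) < 2L)
    oct_error("need at least 2 records to split",
              "octspeckle_insufficient_sample")
  vals <- records[[key]]
  med <- stats::median(vals)
  n_ties <- sum(vals == med)
  below <- records[vals <= med, , drop = FALSE]
  above <- records[vals > med, , drop = FALSE]
  if (nrow(above) == 0L)
    oct_warn(sprintf(
      "all '%s' values are at or below the median; the upper group is empty",
      key))
  structure(list(below = below, above = above, median = med, key = key,
                 n_ties = n_ties), class = "median_split")
}

#' @export
print.median_split <- function(x, ...) {
  cat(sprintf(
    "Median split on %s at %.4g: %d below (incl. %d at the median), %d above\n",
    x$key, x$median, nrow(x$below), x$n_ties, nrow(x$above)))
  invisible(x)
}

#' Compare a variable between two groups (Wilcoxon rank-sum)
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test with normal approximation
#' and tie correction, plus per-group descriptive statistics.
#'
#' @param group1,group2 data frames (e.g. the two halves of a
#'   [median_split()]).
#' @param key variable name to compare.
#' @return list with `p_value`, `statistic` (rank-sum W), `mean1`, `sd1`,
#'   `n1`, `mean2`, `sd2`, `n2`, `key`.
#' @export
group_compare <- function(group1, group2, key) {
  for (g in list(group1, group2))
    if (!is.data.frame(g) || !key %in% names(g))
      oct_error(sprintf("both groups must be data frames with column '%s'",
                        key), "octspeckle_schema_error")
  x1 <- group1[[key]]; x2 <- group2[[key]]
  if (length(x1) < 2L || length(x2) < 2L)
    oct_error("both groups need at least 2 records",
              "octspeckle_insufficient_sample")
  wt <- suppressWarnings(stats::wilcox.test(x1, x2, exact = FALSE,
                                            correct = TRUE))
  list(key = key, p_value = wt$p.value, statistic = unname(wt$statistic),
       mean1 = mean(x1), sd1 = stats::sd(x1), n1 = length(x1),
       mean2 = mean(x2), sd2 = stats::sd(x2), n2 = length(x2))
}

#' Kolmogorov-Smirnov contrast of two Generalised Gamma densities
#'
#' Operationalises a two-sample KS test "between two fitted distributions"
#' by drawing a deterministic pseudo-sample from each: the `m` equispaced
#' mid-quantiles \eqn{q((i - 1/2)/m)} of each GG law. The two pseudo-samples
#' are then compared with the standard two-sample KS test. `m` defaults to
#' 28, a typical half-cohort group size; both the construction and `m` are
#' reported in the result.
#'
#' @param params1,params2 GG parameter sets (named vectors/lists with `a`,
#'   `v`, `p`, or `gg_fit` objects), typically the per-group means of
#'   subject-level parameters.
#' @param m pseudo-sample size per group (default 28).
#' @return list with `statistic` (KS D), `p_value`, `m`, and the two
#'   pseudo-samples.
#' @examples
#' compare_group_pdfs(c(a = .30, v = .43, p = 2.85),
#'                    c(a = .28, v = .44, p = 2.77))
#' @export
compare_group_pdfs <- function(params1, params2, m = 28) {
  get_par <- function(pp) {
    if (inherits(pp, "gg_fit")) pp <- coef(pp)
    pp <- unlist(pp)
    check_gg_params(pp[["a"]], pp[["v"]], pp[["p"]])
    pp
  }
  p1 <- get_par(params1); p2 <- get_par(params2)
  m <- check_count(m, "m", min = 2L)
  probs <- (seq_len(m) - 0.5) / m
  s1 <- qgg(probs, p1[["a"]], p1[["v"]], p1[["p"]])
  s2 <- qgg(probs, p2[["a"]], p2[["v"]], p2[["p"]])
  kt <- suppressWarnings(stats::ks.test(s1, s2))
  list(statistic = unname(kt$statistic), p_value = kt$p.value, m = m,
       pseudo_sample1 = s1, pseudo_sample2 = s2,
       construction = "mid-quantile pseudo-samples")
}
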