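# Group comparisons used to benchmark pump variants: Welch two-sample tests
# (from raw samples or printed summary statistics), t-intervals, Pearson
# correlation and ratios of group means.

#' Group summary statistics
#'
#' Mean, sample standard deviation (n - 1 denominator) and count for one
#' group of per-run values, as printed in benchmark tables.
#'
#' @param label group label.
#' @param mean group mean.
#' @param sd sample standard deviation.
#' @param n number of runs (>= 2).
#' @return object of class `group_summary`.
#' @export
group_summary <- function(label, mean, sd, n) {
  if (n < 2) stop_invalid("a group summary needs n >= 2")
  if (sd < 0) stop_invalid("standard deviation must be non-negative")
  structure(list(label = label, mean = mean, sd = sd, n = as.integer(n)),
            class = "group_summary")
}

#' @rdname group_summary
#' @param x numeric vector of raw per-run values.
#' @export
summarize_group <- function(x, label = "group") {
  group_summary(label, mean(x), stats::sd(x), length(x))
}

as_group_summary <- function(x, label) {
  if (inherits(x, "group_summary")) return(x)
  if (is.numeric(x)) {
    if (length(x) < 2) stop_invalid("each group needs at least 2 values")
    return(summarize_group(x, label))
  }
  stop_invalid("groups must be numeric vectors or group_summary objects")
}

#' Welch two-sample t-test
#'
#' Unequal-variance two-sample t-test with Welch-Satterthwaite (fractional)
#' degrees of freedom. Groups may be raw sample vectors or
#' [group_summary()] objects (mean/sd/n), so tests can be run directly from
#' printed benchmark tables. Identical zero-variance groups return p = 1 by
#' convention; zero variance with unequal means is a degenerate input.
#'
#' @param group_a,group_b numeric vectors or [group_summary()] objects.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (alternatives on mean(a) - mean(b)).
#' @param conf_level confidence level for the interval on the difference in
#'   means.
#' @return object of class `welch_test` with fields `t_statistic`, `df`,
#'   `p_value`, `estimate` (difference in means), `ci` and the group
#'   summaries.
#' @export
welch_test <- function(group_a, group_b,
                       alternative = c("two.sided", "less", "greater"),
                       conf_level = 0.95) {
  alternative <- match.arg(alternative)
  a <- as_group_summary(group_a, "a")
  b <- as_group_summary(group_b, "b")
  va <- a$sd^2 / a$n
  vb <- b$sd^2 / b$n
  diff <- a$mean - b$mean
  if (va + vb == 0) {
    if (diff == 0) {
      t <- 0; df <- a$n + b$n - 2; p <- 1
    } else {
      stop(errorCondition("zero variance in both groups with unequal means",
                          class = c("hemopump_degenerate_input", "error")))
    }
  } else {
    se <- sqrt(va + vb)
    t <- diff / se
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
    p <- switch(alternative,
                two.sided = 2 * stats::pt(-abs(t), df),
                less = stats::pt(t, df),
                greater = stats::pt(t, df, lower.tail = FALSE))
  }
  se <- sqrt(va + vb)
  q <- stats::qt(1 - (1 - conf_level) / 2, df)
  structure(list(t_statistic = t, df = df, p_value = p,
                 estimate = diff, ci = c(diff - q * se, diff + q * se),
                 conf_level = conf_level, alternative = alternative,
                 group_a = a, group_b = b),
            class = "welch_test")
}

#' @export
print.welch_test <- function(x, ...) {
  cat("Welch two-sample t-test (unequal variances)\n")
  cat(sprintf("  t = %.4f, df = %.2f, p (%s) = %.4g\n",
              x$t_statistic, x$df, x$alternative, x$p_value))
  cat(sprintf("  mean difference = %.4g, %d%% CI [%.4g, %.4g]\n",
              x$estimate, round(100 * x$conf_level), x$ci[1], x$ci[2]))
  invisible(x)
}

#' Student t confidence interval for a mean
#'
#' mean +/- t_{n-1, (1+conf)/2} * sd / sqrt(n).
#'
#' @param x numeric vector, length >= 2.
#' @param conf_level confidence level (default 0.95).
#' @return named numeric vector `c(lower, mean, upper)`.
#' @export
t_interval <- function(x, conf_level = 0.95) {
  n <- length(x)
  if (n < 2) stop_invalid("a t-interval needs at least 2 observations")
  m <- mean(x)
  half <- stats::qt(1 - (1 - conf_level) / 2, n - 1) * stats::sd(x) / sqrt(n)
  c(lower = m - half, mean = m, upper = m + half)
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper around [stats::cor()]; errors on constant input
#' where the correlation is undefined.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop_invalid("x and y must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop(errorCondition("correlation undefined for constant input",
                        class = c("hemopump_undefined_correlation", "error")))
  stats::cor(x, y, method = "pearson")
}

#' Ratio of group means
#'
#' mean(a) / mean(b); used to state how many times more hemolysis one pump
#' causes than another.
#'
#' @param group_a,group_b numeric vectors or [group_summary()] objects.
#' @return ratio of means.
#' @export
benchmark_ratio <- function(group_a, group_b) {
  a <- as_group_summary(group_a, "a")
  b <- as_group_summary(group_b, "b")
  if (b$mean == 0) stop_invalid("denominator group has zero mean")
  a$mean / b$mean
}
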