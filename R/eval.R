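#' Per-point 3D Euclidean errors
#'
#' \deqn{Error_i = \sqrt{(x_i-\hat x_i)^2 + (y_i-\hat y_i)^2 + (z_i-\hat z_i)^2}}
#'
#' @param truth Numeric matrix of true coordinates, one row per point,
#'   columns x, y, z (meters).
#' @param prediction Numeric matrix of predicted coordinates, same shape.
#' @return Numeric vector of per-point errors in meters.
#' @export
euclidean_errors <- function(truth, prediction) {
  truth <- as.matrix(truth); prediction <- as.matrix(prediction)
  if (!all(dim(truth) == dim(prediction)))
    stop("'truth' and 'prediction' must have the same shape")
  if (nrow(truth) == 0L) stop("need at least one point")
  if (any(!is.finite(truth)) || any(!is.finite(prediction)))
    stop("coordinates must be finite")
  sqrt(rowSums((truth - prediction)^2))
}

#' Summarize localization errors
#'
#' Computes the standard error report: mean, standard deviation (both the
#' population `1/n` and the sample `1/(n-1)` conventions are reported),
#' median, min, max, and RMSE (`sqrt(mean(errors^2))`, always >= the mean).
#'
#' @param errors Numeric vector of nonnegative per-point errors (meters).
#' @return An object of class `error_report` (a list with fields `n, mean,
#'   sd, sd_pop, median, min, max, rmse, errors`).
#' @export
summarize_errors <- function(errors) {
  if (!is.numeric(errors) || length(errors) == 0L || any(!is.finite(errors)))
    stop("'errors' must be a nonempty finite numeric vector")
  n <- length(errors)
  m <- mean(errors)
  sd_pop <- sqrt(sum((errors - m)^2) / n)
  structure(list(
    n = n, mean = m,
    sd = if (n > 1L) stats::sd(errors) else 0,
    sd_pop = sd_pop,
    median = stats::median(errors),
    min = min(errors), max = max(errors),
    rmse = sqrt(mean(errors^2)),
    errors = errors
  ), class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("Localization error report (n = %d)\n", x$n))
  cat(sprintf("  mean   %.4f m  (sd %.4f sample / %.4f population)\n",
              x$mean, x$sd, x$sd_pop))
  cat(sprintf("  median %.4f m   min %.4f   max %.4f   rmse %.4f\n",
              x$median, x$min, x$max, x$rmse))
  invisible(x)
}

#' Mean per-axis relative error
#'
#' For each axis, the mean over points of `|pred - truth| / |truth|`,
#' expressed as a percentage. Points with a zero true coordinate on an axis
#' are excluded on that axis with a warning (the ratio is undefined there).
#'
#' @inheritParams euclidean_errors
#' @return Named numeric vector `c(x =, y =, z =)` of percentages.
#' @export
per_axis_relative_error <- function(truth, prediction) {
  truth <- as.matrix(truth); prediction <- as.matrix(prediction)
  if (!all(dim(truth) == dim(prediction)))
    stop("'truth' and 'prediction' must have the same shape")
  if (ncol(truth) != 3L) stop("expected 3 coordinate columns")
  out <- numeric(3L)
  for (a in 1:3) {
    ok <- truth[, a] != 0
    if (!all(ok))
      warning(sum(!ok), " point(s) with zero true coordinate excluded on axis ", a)
    if (!any(ok)) { out[a] <- NA_real_; next }
    out[a] <- 100 * mean(abs(prediction[ok, a] - truth[ok, a]) / abs(truth[ok, a]))
  }
  names(out) <- c("x", "y", "z")
  out
}

#' Percentage reduction between two error levels
#'
#' `100 * (before - after) / before`; positive when `after` improves on
#' `before`.
#'
#' @param before Baseline error (must be > 0).
#' @param after Improved error.
#' @return Percentage reduction.
#' @export
pct_reduction <- function(before, after) {
  if (any(before <= 0)) stop("'before' must be positive")
  100 * (before - after) / before
}

#' Paired two-tailed t-test on per-point errors
#'
#' Tests whether method `a`'s per-point errors differ from method `b`'s
#' using the paired differences `d_i = a_i - b_i`:
#' `t = mean(d) / (sd(d)/sqrt(n))` with `df = n - 1` and the sample-SD
#' convention. The effect size is Cohen's d of the paired differences,
#' `mean(d)/sd(d)`. Both t and the effect size are negative when method `a`
#' has the smaller errors. Zero-variance differences give a degenerate
#' result flagged via `degenerate = TRUE` (t = 0, p = 1 when the means also
#' agree).
#'
#' @param errors_a,errors_b Equal-length numeric vectors of paired errors.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `paired_test_result`: list with `t_statistic,
#'   p_value, significant, effect_size, df, alpha, mean_diff, degenerate`.
#' @export
paired_t_test <- function(errors_a, errors_b, alpha = 0.05) {
  if (length(errors_a) != length(errors_b))
    stop("paired samples must have equal length")
  n <- length(errors_a)
  if (n < 2L) stop("need at least 2 pairs")
  d <- errors_a - errors_b
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    res <- list(t_statistic = 0, p_value = 1, significant = FALSE,
                effect_size = 0, df = n - 1L, alpha = alpha,
                mean_diff = mean(d), degenerate = TRUE)
    return(structure(res, class = "paired_test_result"))
  }
  t_stat <- mean(d) / (sd_d / sqrt(n))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  structure(list(t_statistic = t_stat, p_value = p,
                 significant = p < alpha,
                 effect_size = mean(d) / sd_d,
                 df = n - 1L, alpha = alpha,
                 mean_diff = mean(d), degenerate = FALSE),
            class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf("Paired t-test: t = %.3f, df = %d, p = %.4g (%ssignificant at alpha = %g)\n",
              x$t_statistic, x$df, x$p_value,
              if (x$significant) "" else "not ", x$alpha))
  cat(sprintf("  effect size (Cohen's d of differences) = %.3f%s\n",
              x$effect_size, if (x$degenerate) "  [degenerate: zero-variance differences]" else ""))
  invisible(x)
}

#' Full evaluation report for a set of predictions
#'
#' Convenience wrapper: Euclidean errors, summary statistics and per-axis
#' relative errors in one object, serializable to JSON.
#'
#' @inheritParams euclidean_errors
#' @return A list with components `summary` ([summarize_errors()]),
#'   `per_axis_rel` ([per_axis_relative_error()]) and `errors`.
#' @export
evaluate_positions <- function(truth, prediction) {
  e <- euclidean_errors(truth, prediction)
  list(summary = summarize_errors(e),
       per_axis_rel = per_axis_relative_error(truth, prediction),
       errors = e)
}
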