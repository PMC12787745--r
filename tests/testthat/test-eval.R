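test_that("Euclidean errors match hand values and the benchmark table", {
  expect_equal(euclidean_errors(rbind(c(1, 2, 3)), rbind(c(1, 2, 3))), 0)
  expect_equal(euclidean_errors(rbind(c(0, 0, 0)), rbind(c(1, 2, 2))), 3)
  # benchmark point 5: truth (1.20, 1.20, 1.30) vs dual-stream (1.22, 1.21, 1.30)
  bp <- tagloc_benchmark_positions()
  truth <- as.matrix(bp[bp$model == "truth", c("x", "y", "z")])
  dtr <- as.matrix(bp[bp$model == "dtr", c("x", "y", "z")])
  e <- euclidean_errors(truth, dtr)
  expect_equal(unname(e[5]), sqrt(0.02^2 + 0.01^2), tolerance = 1e-12)
  expect_equal(unname(round(e[5], 3)), 0.022)
})

test_that("error summaries match an independent summation oracle", {
  s <- summarize_errors(c(3, 3, 3))
  expect_equal(s$mean, 3); expect_equal(s$sd, 0); expect_equal(s$rmse, 3)
  s <- summarize_errors(c(0, 4))
  expect_equal(s$mean, 2)
  expect_equal(s$rmse, sqrt(8))
  expect_gte(s$rmse, s$mean)
  set.seed(41)
  for (i in 1:10) {
    e <- abs(rnorm(sample(5:50, 1), 0.3, 0.2))
    s <- summarize_errors(e)
    n <- length(e)
    m <- sum(e) / n
    expect_equal(s$mean, m, tolerance = 1e-12)
    expect_equal(s$sd_pop, sqrt(sum((e - m)^2) / n), tolerance = 1e-12)
    expect_equal(s$sd, sqrt(sum((e - m)^2) / (n - 1)), tolerance = 1e-12)
    expect_equal(s$rmse, sqrt(sum(e^2) / n), tolerance = 1e-12)
    expect_gte(s$rmse, s$mean - 1e-12)  # Jensen
    expect_true(s$min <= s$median && s$median <= s$max)
  }
})

test_that("per-axis relative errors reproduce the dual-stream benchmark", {
  bp <- tagloc_benchmark_positions()
  truth <- as.matrix(bp[bp$model == "truth", c("x", "y", "z")])
  dtr <- as.matrix(bp[bp$model == "dtr", c("x", "y", "z")])
  rel <- per_axis_relative_error(truth, dtr)
  expect_equal(unname(rel[1]), 6.118, tolerance = 0.005)
  expect_equal(unname(rel[2]), 3.311, tolerance = 0.005)
  expect_equal(unname(rel[3]), 2.143, tolerance = 0.005)
})

test_that("per-axis relative error is scale invariant and handles zeros", {
  set.seed(42)
  truth <- matrix(runif(30, 0.5, 3), 10)
  pred <- truth + matrix(rnorm(30, 0, 0.1), 10)
  r1 <- per_axis_relative_error(truth, pred)
  r2 <- per_axis_relative_error(7 * truth, 7 * pred)
  expect_equal(r1, r2, tolerance = 1e-12)
  expect_equal(unname(per_axis_relative_error(truth, truth)), c(0, 0, 0))
  expect_equal(unname(per_axis_relative_error(rbind(c(2, 2, 2)),
                                              rbind(c(2.2, 2, 2)))),
               c(10, 0, 0), tolerance = 1e-12)
  truth[1, 1] <- 0
  expect_warning(per_axis_relative_error(truth, pred), "zero true coordinate")
})

test_that("percentage reductions behave algebraically", {
  expect_equal(pct_reduction(0.5, 0.5), 0)
  for (r in c(0, 10, 33.3, 99)) {
    expect_equal(pct_reduction(2, 2 * (1 - r / 100)), r, tolerance = 1e-12)
  }
  expect_error(pct_reduction(0, 1), "positive")
})

test_that("ablation summary rows reproduce all twelve printed reductions", {
  ab <- tagloc_ablation_summary()
  full <- ab[ab$gain & ab$dtr, ]          # imputation + dual-stream locator
  dtr_only <- ab[!ab$gain & ab$dtr, ]
  lm_gain <- ab[ab$landmarc & ab$gain, ]
  lm_raw <- ab[ab$landmarc & !ab$gain, ]
  cols <- c("mean_error_m", "sd_error_m", "max_error_m", "min_error_m")
  red <- function(b) round(pct_reduction(unlist(b[cols]), unlist(full[cols])), 2)
  expect_equal(unname(red(dtr_only)), c(14.14, 66.67, 24.60, 59.26))
  expect_equal(unname(red(lm_gain)), c(78.04, 80.26, 83.27, 94.53))
  expect_equal(unname(red(lm_raw)), c(81.32, 82.95, 84.69, 94.79))
})

test_that("paired t-test matches the closed form and stats::t.test", {
  set.seed(43)
  a <- abs(rnorm(10, 0.3, 0.1)); b <- abs(rnorm(10, 0.5, 0.2))
  res <- paired_t_test(a, b)
  d <- a - b
  t_closed <- mean(d) / (sd(d) / sqrt(10))
  expect_equal(res$t_statistic, t_closed, tolerance = 1e-6)
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(res$t_statistic, unname(ref$statistic), tolerance = 1e-6)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-6)
  expect_equal(res$df, 9L)
  expect_equal(res$effect_size, mean(d) / sd(d), tolerance = 1e-12)
})

test_that("paired t-test is antisymmetric and flags degenerate input", {
  set.seed(44)
  a <- abs(rnorm(12)); b <- abs(rnorm(12))
  r1 <- paired_t_test(a, b); r2 <- paired_t_test(b, a)
  expect_equal(r1$t_statistic, -r2$t_statistic, tolerance = 1e-12)
  expect_equal(r1$effect_size, -r2$effect_size, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  deg <- paired_t_test(a, a)
  expect_true(deg$degenerate)
  expect_equal(deg$t_statistic, 0)
  expect_error(paired_t_test(a, a[-1]), "equal length")
})

test_that("significance pattern on the benchmark table favours the dual-stream model", {
  bp <- tagloc_benchmark_positions()
  truth <- as.matrix(bp[bp$model == "truth", c("x", "y", "z")])
  errs <- lapply(c("dtr", "str", "tcn", "gru", "lstm"), function(mo)
    euclidean_errors(truth, as.matrix(bp[bp$model == mo, c("x", "y", "z")])))
  names(errs) <- c("dtr", "str", "tcn", "gru", "lstm")
  for (other in c("str", "tcn", "gru", "lstm")) {
    res <- paired_t_test(errs$dtr, errs[[other]])
    expect_lt(res$t_statistic, 0)
    expect_lt(res$effect_size, 0)
  }
})
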