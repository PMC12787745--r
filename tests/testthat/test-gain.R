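# small complete data matrix of plausible RSSI windows for imputer tests
gain_fixture <- function(n = 200, L = 9, seed = 51) {
  cfg <- scene_config()
  ds <- make_training_set(cfg, n, T_win = L - 1L, mode = "clean", seed = seed)
  ds$rssi[, , 1L]  # windows from the first antenna
}

test_that("masked batches satisfy the mask/data/noise identities", {
  X <- gain_fixture(50)
  b <- make_masked_batch(X, missing_rate = 0.3, seed = 1)
  expect_true(all(b$M %in% c(0, 1)))
  expect_true(all(b$X * (1 - b$M) == 0))
  expect_true(all(b$Z * b$M == 0))
  expect_equal(b$X[b$M == 1], b$truth[b$M == 1])
  b0 <- make_masked_batch(X, missing_rate = 0, seed = 1)
  expect_true(all(b0$M == 1))
  expect_true(all(b0$Z == 0))
  expect_equal(b0$X, X)
  expect_error(make_masked_batch(X, 1), "missing_rate")
})

test_that("masking rate honours its Bernoulli law", {
  X <- matrix(0, 100, 100)
  b <- make_masked_batch(X, missing_rate = 0.3, seed = 2)
  obs <- mean(b$M)
  expect_lt(abs(obs - 0.7), qnorm(0.995) * sqrt(0.3 * 0.7 / 1e4))
})

test_that("hint matrices reveal the mask at the hint rate", {
  M <- matrix(rbinom(1e4, 1, 0.5), 100)
  expect_equal(hint_from_mask(M, hint_rate = 1, seed = 3), M)
  H <- hint_from_mask(M, hint_rate = 0.9, seed = 3)
  expect_true(all(H %in% c(0, 0.5, 1)))
  frac_half <- mean(H == 0.5)
  expect_lt(abs(frac_half - 0.1), qnorm(0.995) * sqrt(0.1 * 0.9 / 1e4))
})

test_that("imputation preserves observed entries for any generator state", {
  X <- gain_fixture(40)
  gain <- tagloc3d:::gain_new(gain_config("desk"), ncol(X), seed = 4)
  b <- make_masked_batch(X, 0.4, seed = 5)
  imp <- gain_impute(gain, b)
  expect_identical(imp$X_hat * b$M, b$X * b$M)
  expect_equal(imp$X_hat[b$M == 1], X[b$M == 1])
  # all-observed and all-missing limits
  b1 <- make_masked_batch(X, 0, seed = 6)
  expect_equal(gain_impute(gain, b1)$X_hat, X)
  b0 <- b1; b0$M <- b0$M * 0; b0$X <- b0$X * 0
  b0$Z <- matrix(rnorm(length(X)), nrow(X))
  imp0 <- gain_impute(gain, b0)
  expect_equal(imp0$X_hat, imp0$X_bar)
})

test_that("batches built from NA matrices reconstruct the mask", {
  X <- gain_fixture(30)
  Xna <- X; Xna[sample(length(X), 80)] <- NA
  b <- masked_batch_from_na(Xna, seed = 7)
  expect_equal(b$M == 0, is.na(Xna))
  expect_true(all(b$X[is.na(Xna)] == 0))
})

test_that("a short adversarial run is seeded, finite and mask-consistent", {
  X <- gain_fixture(150)
  cfg <- gain_config("desk", gen_widths = c(32, 64, 32), disc_widths = c(32),
                     epochs = 15)
  g1 <- train_gain(X, cfg = cfg, missing_rate = 0.3, seed = 8)
  g2 <- train_gain(X, cfg = cfg, missing_rate = 0.3, seed = 8)
  expect_equal(g1$history, g2$history, tolerance = 1e-12)
  expect_true(all(is.finite(g1$history$g_loss)))
  expect_true(all(is.finite(g1$history$d_loss)))
  b <- make_masked_batch(X, 0.3, seed = 9)
  imp <- gain_impute(g1, b)
  expect_equal(imp$X_hat * b$M, b$X * b$M, tolerance = 1e-12)
  # the short run should already improve on an untrained generator
  rmse_gain <- imputation_rmse(imp$X_hat, b)
  g0 <- tagloc3d:::gain_new(cfg, ncol(X), seed = 8)
  g0$standardizer <- g1$standardizer
  rmse_untrained <- imputation_rmse(gain_impute(g0, b)$X_hat, b)
  expect_lt(rmse_gain, rmse_untrained)
})

test_that("zero-variance training data does not crash the imputer", {
  X <- matrix(-60, 50, 9)
  cfg <- gain_config("desk", gen_widths = c(16, 16), disc_widths = c(16),
                     epochs = 5)
  g <- expect_no_error(train_gain(X, cfg = cfg, seed = 10))
  b <- make_masked_batch(X, 0.3, seed = 11)
  imp <- gain_impute(g, b)
  expect_true(all(is.finite(imp$X_hat)))
})

test_that("conditioning features follow the path-loss model", {
  m <- path_loss_model(-54.42, 1.218)
  pos <- rbind(c(0, 0, 0), c(1, 1, 0.5))
  ant <- c(0, 0, 2.4)
  cond <- pathloss_conditioning(m, pos, ant)
  expect_equal(dim(cond), c(2L, 4L))
  d1 <- 2.4
  expect_equal(unname(cond[1, 3]), predict_rssi(m, d1))
  expect_equal(unname(cond[1, 4]), -10 * 1.218 / (d1 * log(10)))
  # conditioned model requires the matrix at imputation time
  X <- gain_fixture(20)
  g <- tagloc3d:::gain_new(gain_config("desk"), ncol(X), cond_dim = 4L)
  b <- make_masked_batch(X, 0.3, seed = 12)
  expect_error(gain_impute(g, b), "conditioning")
})

test_that("baseline imputers fill only missing entries, interpolating in time", {
  X <- rbind(c(1, 2, 3, 4, 5), c(10, 20, 30, 40, 50))
  M <- rbind(c(1, 0, 1, 1, 1), c(1, 1, 0, 0, 1))
  cm <- impute_column_mean(X * M, M)
  expect_equal(cm[1, 2], 20)            # column mean of observed (only row 2)
  expect_equal(cm[M == 1], X[M == 1])
  li <- impute_linear_interp(X * M, M)
  expect_equal(li[1, 2], 2)             # between 1 and 3
  expect_equal(li[2, 3:4], c(30, 40))   # between 20 and 50
  expect_equal(li[M == 1], X[M == 1])
  # edge extrapolation is constant
  M2 <- rbind(c(0, 1, 1, 1, 0))
  li2 <- impute_linear_interp(rbind(c(0, 2, 3, 4, 0)), M2)
  expect_equal(as.numeric(li2), c(2, 2, 3, 4, 4))
})

test_that("dual-channel matrices keep RSSI and differential channels aligned", {
  W <- gain_fixture(25, L = 6)
  D <- gain_dual_channel_matrix(W)
  expect_equal(ncol(D), 11L)
  expect_equal(D[4, 7:11], diff(W[4, ]), tolerance = 1e-12)
  expect_equal(gain_diff_consistency(D, 6), 0, tolerance = 1e-12)
  D2 <- D; D2[, 7] <- D2[, 7] + 1
  expect_equal(gain_diff_consistency(D2, 6), 1 / 5, tolerance = 1e-12)
})
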