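det_cfg <- function(...) {
  scene_config(pathloss = path_loss_model(-54.42, 1.218, sigma_shadow = 0), ...)
}

test_that("noiseless logs equal the closed-form path-loss values", {
  cfg <- det_cfg()
  sim <- simulate_log(cfg, 50, seed = 5)
  ants <- cfg$antennas
  for (i in sample(nrow(sim$log), 40)) {
    row <- sim$log[i, ]
    tr <- sim$truth[sim$truth$timestamp == row$timestamp, ]
    d <- sqrt(sum((c(tr$x, tr$y, tr$z) - ants[row$antenna_id, ])^2))
    expect_equal(row$rssi_dbm, predict_rssi(cfg$pathloss, max(d, 1e-3)),
                 tolerance = 1e-12)
  }
})

test_that("baseline missingness matches its Bernoulli rate", {
  cfg <- det_cfg(missing_rate = 0.3)
  sim <- simulate_log(cfg, 2500, seed = 6)   # 10^4 readings over 4 antennas
  n <- nrow(sim$log)
  miss <- sum(is.na(sim$log$rssi_dbm))
  ci <- qnorm(0.995) * sqrt(0.3 * 0.7 / n)
  expect_lt(abs(miss / n - 0.3), ci)
})

test_that("occlusion zones raise the dropout rate along blocked paths", {
  # a slab between the arena and the antennas occludes every reading
  box <- c(-5, 5, -5, 5, 1.5, 2.0)
  cfg <- det_cfg(missing_rate = 0.05, occlusion_zones = list(box),
                 occlusion_dropout = 0.8)
  sim <- simulate_log(cfg, 1000, seed = 7)
  miss_rate <- mean(is.na(sim$log$rssi_dbm))
  expect_gt(miss_rate, 0.7)
  expect_lt(miss_rate, 0.9)
})

test_that("simulated calibration data recover the scene parameters", {
  cfg <- scene_config()  # sigma 2 dB shadow fading
  set.seed(8)
  m <- cfg$pathloss
  ring <- predict_rssi(m, rep(1, 1000))
  A_hat <- calibrate_A(ring)
  expect_lt(abs(A_hat - m$A), 0.3)
  d <- runif(1000, 0.5, 5)
  n_hat <- calibrate_n(m$A, predict_rssi(m, d), d, robust = "ols")
  expect_lt(abs(n_hat - m$n), 0.05)
})

test_that("reference grids have product cardinality and exact noiseless values", {
  cfg <- det_cfg(ref_spacing = 0.5)
  refs <- make_reference_fingerprints(cfg, seed = 9)
  n_axis <- vapply(1:3, function(a)
    length(seq(cfg$arena[2 * a - 1], cfg$arena[2 * a], by = 0.5)), integer(1))
  expect_equal(nrow(refs$positions), prod(n_axis))
  i <- 17
  d <- sqrt(colSums((t(cfg$antennas) - refs$positions[i, ])^2))
  expect_equal(refs$fingerprints[i, ], unname(predict_rssi(cfg$pathloss, d)),
               tolerance = 1e-12)
  # spacing >= extent degenerates to a single central tag per axis
  cfg1 <- det_cfg(ref_spacing = 10)
  refs1 <- make_reference_fingerprints(cfg1, seed = 9)
  expect_equal(nrow(refs1$positions), 1L)
  expect_equal(unname(refs1$positions[1, ]), c(0, 0, 0.5))
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- scene_config(missing_rate = 0.2)
  s1 <- simulate_log(cfg, 100, seed = 10)
  s2 <- simulate_log(cfg, 100, seed = 10)
  expect_identical(s1, s2)
  s3 <- simulate_log(cfg, 100, seed = 11)
  expect_false(identical(s1$log$rssi_dbm, s3$log$rssi_dbm))
  ds1 <- make_training_set(cfg, 50, T_win = 8, seed = 12)
  ds2 <- make_training_set(cfg, 50, T_win = 8, seed = 12)
  expect_identical(ds1, ds2)
})

test_that("empirical mean RSSI converges to the deterministic value", {
  m <- path_loss_model(-54.42, 1.218, sigma_shadow = 2)
  set.seed(13)
  draws <- predict_rssi(m, rep(2.5, 1e4))
  mu <- m$A - 10 * m$n * log10(2.5)
  expect_lt(abs(mean(draws) - mu), qnorm(0.995) * 2 / sqrt(1e4))
  expect_lt(abs(sd(draws) - 2), 0.1)
})

test_that("mean RSSI decreases with distance across the reference grid", {
  cfg <- scene_config()
  refs <- make_reference_fingerprints(cfg, n_avg = 50, seed = 14)
  for (h in 1:4) {
    d <- sqrt(colSums((t(refs$positions) - cfg$antennas[h, ])^2))
    expect_lt(cor(d, refs$fingerprints[, h], method = "spearman"), -0.9)
  }
})

test_that("training windows align diffs, targets and trajectory", {
  cfg <- det_cfg()
  ds <- make_training_set(cfg, 40, T_win = 8, mode = "clean", seed = 15)
  expect_equal(dim(ds$rssi), c(40, 9, 4))
  expect_equal(dim(ds$diff), c(40, 8, 4))
  expect_equal(ds$diff[3, , 2], diff(ds$rssi[3, , 2]), tolerance = 1e-12)
  # clean mode never drops readings
  expect_false(any(is.na(ds$rssi)))
  # default stride: windows tile the trajectory without overlap
  ds1 <- make_training_set(cfg, 40, T_win = 8, mode = "clean", stride = 1,
                           seed = 15)
  expect_equal(ds1$rssi[2, 1:8, 1], ds1$rssi[1, 2:9, 1], tolerance = 1e-12)
  expect_equal(ds$rssi[1, , 1], ds1$rssi[1, , 1], tolerance = 1e-12)
})

test_that("drop mode leaves explicit missing entries for the imputer", {
  cfg <- det_cfg(missing_rate = 0.3)
  ds <- make_training_set(cfg, 60, T_win = 8, mode = "drop", seed = 16)
  expect_gt(mean(is.na(ds$rssi)), 0.2)
  filled <- make_training_set(cfg, 60, T_win = 8, mode = "impute",
                              imputer = function(X) {
                                X[is.na(X)] <- -60; X
                              }, seed = 16)
  expect_false(any(is.na(filled$rssi)))
})
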