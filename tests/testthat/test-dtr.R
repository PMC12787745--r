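tiny_ds <- function(n = 10, T_win = 8, seed = 61) {
  make_training_set(scene_config(), n, T_win = T_win, mode = "clean",
                    seed = seed)
}

test_that("first differences subtract successive elements and telescope", {
  expect_equal(first_diff(c(-50, -50, -50)), c(0, 0))
  expect_equal(first_diff(c(-50, -52, -49)), c(-2, 3))
  set.seed(62)
  for (i in 1:10) {
    s <- rnorm(sample(2:30, 1))
    expect_equal(s[1] + cumsum(c(0, first_diff(s))), s, tolerance = 1e-12)
  }
  m <- matrix(1:12, 4)
  expect_equal(first_diff(m), m[-1, ] - m[-4, ])
  expect_error(first_diff(1), "at least 2")
})

test_that("locator forward passes are deterministic and head-linear", {
  cfg <- dtr_config("desk", layers = 1, d = 16, heads = 2, T_win = 8,
                    epochs = 2, batch_size = 5)
  ds <- tiny_ds()
  m <- build_locator(cfg, 4, seed = 1)
  m <- train_locator(m, ds, seed = 1)
  p1 <- predict_positions(m, ds)
  p2 <- predict_positions(m, ds)
  expect_identical(p1, p2)
  # zeroing the head weights leaves only the output bias (plus target
  # de-standardization)
  m0 <- m
  m0$head$params$W1[] <- 0
  m0$head$params$W2[] <- 0
  p0 <- predict_positions(m0, ds)
  act <- tagloc3d:::.act_fun("gelu")$f(m0$head$params$b1)
  bias_out <- as.numeric(act %*% m0$head$params$W2) + m0$head$params$b2
  st <- m0$standardizer
  expected <- bias_out * st$sd_y + st$mu_y
  for (i in 1:3) expect_equal(unname(p0[i, ]), unname(expected),
                              tolerance = 1e-10)
})

test_that("permuting antenna channels with matching input rows is a no-op", {
  cfg <- dtr_config("desk", layers = 1, d = 16, heads = 2, T_win = 8,
                    epochs = 2, batch_size = 5)
  ds <- tiny_ds()
  m <- build_locator(cfg, 4, seed = 2)
  m <- train_locator(m, ds, seed = 2)
  p1 <- predict_positions(m, ds)
  perm <- c(3, 1, 4, 2)
  ds2 <- ds
  ds2$rssi <- ds$rssi[, , perm]
  ds2$diff <- ds$diff[, , perm]
  m2 <- m
  m2$enc_raw$params$Wi <- m$enc_raw$params$Wi[perm, ]
  m2$enc_diff$params$Wi <- m$enc_diff$params$Wi[perm, ]
  p2 <- predict_positions(m2, ds2)
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("training is reproducible under a fixed seed", {
  cfg <- dtr_config("desk", layers = 1, d = 16, heads = 2, T_win = 8,
                    epochs = 3, batch_size = 5)
  ds <- tiny_ds()
  m1 <- train_locator(build_locator(cfg, 4, seed = 3), ds, seed = 3)
  m2 <- train_locator(build_locator(cfg, 4, seed = 3), ds, seed = 3)
  expect_equal(m1$head$params, m2$head$params, tolerance = 1e-15)
  expect_equal(m1$enc_raw$params$Wi, m2$enc_raw$params$Wi, tolerance = 1e-15)
  expect_equal(m1$history$loss, m2$history$loss, tolerance = 1e-15)
  m3 <- train_locator(build_locator(cfg, 4, seed = 4), ds, seed = 4)
  expect_false(isTRUE(all.equal(m1$head$params$W2, m3$head$params$W2)))
})

test_that("training loss trends downward from the start on the overfit fixture", {
  cfg <- dtr_config("desk", T_win = 8, epochs = 12, batch_size = 10)
  ds <- tiny_ds()
  m <- train_locator(build_locator(cfg, 4, seed = 5), ds, seed = 5)
  h <- m$history$loss
  expect_lt(h[10], h[1])
  # no epoch-to-epoch blow-ups early on
  expect_true(all(diff(h[1:10]) < 0.05 * h[1] + 1e-8))
})

test_that("every baseline architecture trains on the overfit fixture", {
  cfg <- dtr_config("desk", layers = 1, d = 16, heads = 2, T_win = 8,
                    epochs = 2, batch_size = 5)
  ds <- tiny_ds()
  for (kind in c("single_transformer", "gru", "lstm", "tcn")) {
    m <- build_baseline(kind, cfg, 4, seed = 6)
    m <- expect_no_error(train_locator(m, ds, seed = 6))
    p <- predict_positions(m, ds)
    expect_true(all(is.finite(p)))
    expect_equal(dim(p), c(10L, 3L))
  }
})

test_that("the single-stream model is the dual model minus the diff stream", {
  cfg <- dtr_config("desk")
  s <- build_baseline("single_transformer", cfg, 4, seed = 7)
  d <- build_locator(cfg, 4, seed = 7)
  expect_identical(s$kind, "str")
  expect_null(s$enc_diff)
  expect_false(is.null(d$enc_diff))
  # identical raw-stream architecture
  expect_identical(dim(s$enc_raw$params$Wi), dim(d$enc_raw$params$Wi))
  expect_identical(s$enc_raw$n_layers, d$enc_raw$n_layers)
})

test_that("baseline parameter budgets are within a factor two of the dual model", {
  cfg <- dtr_config("desk")
  ref <- n_parameters(build_locator(cfg, 4, seed = 8))
  for (kind in c("single_transformer", "gru", "lstm", "tcn")) {
    n <- n_parameters(build_baseline(kind, cfg, 4, seed = 8))
    ratio <- max(ref / n, n / ref)
    expect_lt(ratio, 2)
  }
})

test_that("sequence-length bookkeeping rejects mismatched samples", {
  cfg <- dtr_config("desk", layers = 1, d = 16, heads = 2, T_win = 8,
                    epochs = 2, batch_size = 5)
  ds <- tiny_ds()
  m <- train_locator(build_locator(cfg, 4, seed = 9), ds, seed = 9)
  bad <- tiny_ds(T_win = 6)
  expect_error(predict_positions(m, bad))
})
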