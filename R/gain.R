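#' GAIN configuration
#'
#' Hyperparameters for the generative adversarial imputation network. The
#' `"paper"` profile uses the field-scale setup: generator widths
#' 256-512-1024-512, 128-dimensional Gaussian noise input, learning rate
#' 2e-4, batch 64, 2000 epochs. The `"desk"` profile quarters the widths
#' (64-128-256-128), drops the extra noise input and trains 200 epochs, so
#' a run takes well under a CPU-minute. The discriminator is a dense
#' per-entry stack (it predicts, for every matrix entry, the probability
#' that the entry was observed rather than imputed).
#'
#' @param profile `"desk"` or `"paper"`.
#' @param gen_widths Generator hidden-layer widths.
#' @param disc_widths Discriminator hidden-layer widths.
#' @param lr Learning rate (both networks).
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param hint_rate Probability a mask entry is revealed to the
#'   discriminator (default 0.9).
#' @param alpha Weight of the observed-entry reconstruction loss in the
#'   generator objective (default 10).
#' @param noise_dim Extra Gaussian noise inputs to the generator.
#' @param z_scale Factor applied to the random matrix before it enters the
#'   generator (default 0.01, the reference GAIN convention: the per-entry
#'   noise acts as a small dither, keeping the learned imputation map
#'   near-deterministic given the observed entries).
#' @param center `"window"` (default) or `"column"`. RSSI windows share a
#'   physical level set by the tag--antenna geometry, so each row is
#'   centred on the mean of its observed entries before the per-column
#'   standardization; the generator then models residual structure, and
#'   the level is restored on output. Use `"column"` for heterogeneous
#'   row layouts (e.g. dual-channel matrices), where a row mean mixes
#'   scales.
#' @return An object of class `gain_config`.
#' @export
gain_config <- function(profile = c("desk", "paper"), gen_widths = NULL,
                        disc_widths = NULL, lr = 2e-4, batch_size = 64,
                        epochs = NULL, hint_rate = 0.9, alpha = 10,
                        noise_dim = NULL, z_scale = 0.01,
                        center = c("window", "column")) {
  center <- match.arg(center)
  profile <- match.arg(profile)
  if (profile == "paper") {
    gen_widths <- gen_widths %||% c(256L, 512L, 1024L, 512L)
    disc_widths <- disc_widths %||% c(512L, 256L, 128L)
    epochs <- epochs %||% 2000L
    noise_dim <- noise_dim %||% 128L
  } else {
    gen_widths <- gen_widths %||% c(64L, 128L, 256L, 128L)
    disc_widths <- disc_widths %||% c(128L, 64L)
    epochs <- epochs %||% 200L
    noise_dim <- noise_dim %||% 0L
  }
  if (any(gen_widths <= 0) || any(disc_widths <= 0)) stop("widths must be positive")
  if (hint_rate <= 0 || hint_rate > 1) stop("'hint_rate' must be in (0, 1]")
  if (lr <= 0) stop("'lr' must be positive")
  if (z_scale < 0) stop("'z_scale' must be nonnegative")
  structure(list(profile = profile, gen_widths = as.integer(gen_widths),
                 disc_widths = as.integer(disc_widths), lr = lr,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), hint_rate = hint_rate,
                 alpha = alpha, noise_dim = as.integer(noise_dim),
                 z_scale = z_scale, center = center),
            class = "gain_config")
}

#' Create a masked batch from complete data
#'
#' Draws a Bernoulli(1 - missing_rate) mask per entry and splits the data
#' into the GAIN triplet: data matrix `X` (masked entries zeroed), mask
#' `M` (1 = present), and random matrix `Z` (standard normal at masked
#' entries, zero elsewhere).
#'
#' @param complete Numeric matrix without missing entries.
#' @param missing_rate Fraction of entries to mask, in `[0, 1)`.
#' @param seed Integer seed.
#' @return An object of class `masked_batch`: list `X, M, Z, truth`.
#' @export
make_masked_batch <- function(complete, missing_rate, seed = 1) {
  complete <- as.matrix(complete)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("'missing_rate' must be in [0, 1)")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  M <- matrix(stats::rbinom(length(complete), 1L, 1 - missing_rate),
              nrow(complete))
  Z <- matrix(stats::rnorm(length(complete)), nrow(complete)) * (1 - M)
  structure(list(X = complete * M, M = M, Z = Z, truth = complete),
            class = "masked_batch")
}

#' Masked batch from data with explicit missing entries
#'
#' Converts a matrix with `NA`s into the GAIN triplet (no ground truth).
#'
#' @param X_na Numeric matrix, `NA` = missing.
#' @param seed Integer seed for the random matrix.
#' @return A `masked_batch` with `truth = NULL`.
#' @export
masked_batch_from_na <- function(X_na, seed = 1) {
  X_na <- as.matrix(X_na)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  M <- 1 - is.na(X_na) * 1
  X <- X_na; X[is.na(X)] <- 0
  Z <- matrix(stats::rnorm(length(X)), nrow(X)) * (1 - M)
  structure(list(X = X, M = M, Z = Z, truth = NULL), class = "masked_batch")
}

#' Hint matrix from a mask
#'
#' Canonical GAIN hint: each mask entry is revealed to the discriminator
#' with probability `hint_rate`; unrevealed entries are set to 0.5, so the
#' hint takes values in {0, 0.5, 1}.
#'
#' @param M Binary mask matrix.
#' @param hint_rate Reveal probability in (0, 1].
#' @param seed Integer seed.
#' @return Hint matrix, same shape as `M`.
#' @export
hint_from_mask <- function(M, hint_rate = 0.9, seed = 1) {
  if (hint_rate <= 0 || hint_rate > 1) stop("'hint_rate' must be in (0, 1]")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  B <- matrix(stats::rbinom(length(M), 1L, hint_rate), nrow(M))
  B * M + 0.5 * (1 - B)
}

# fresh (untrained) GAIN pair for a given data dimension
gain_new <- function(cfg, data_dim, cond_dim = 0L, seed = 1) {
  stopifnot(inherits(cfg, "gain_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  g_in <- 3L * data_dim + cond_dim + cfg$noise_dim
  G <- mlp_new(c(g_in, cfg$gen_widths, data_dim),
               c(rep("relu", length(cfg$gen_widths)), "identity"))
  D <- mlp_new(c(2L * data_dim, cfg$disc_widths, data_dim),
               c(rep("relu", length(cfg$disc_widths)), "sigmoid"))
  structure(list(cfg = cfg, data_dim = data_dim, cond_dim = cond_dim,
                 G = G, D = D,
                 standardizer = list(mu = rep(0, data_dim),
                                     sd = rep(1, data_dim)),
                 history = NULL),
            class = "gain_model")
}

#' @export
print.gain_model <- function(x, ...) {
  cat(sprintf("GAIN model (%s profile): data dim %d, conditioning dim %d%s\n",
              x$cfg$profile, x$data_dim, x$cond_dim,
              if (is.null(x$history)) " (untrained)" else
                sprintf(" (trained %d epochs)", max(x$history$epoch))))
  invisible(x)
}

# per-row level: mean of observed entries (0 when a row has none)
.row_level <- function(X, M) {
  n_obs <- rowSums(M)
  lv <- rowSums(X * M) / pmax(n_obs, 1)
  lv[n_obs == 0] <- 0
  lv
}

# generator input on the standardized scale
.gain_g_input <- function(gain, Xs, M, Z, conditioning, noise = NULL) {
  inp <- cbind(Xs, M, (1 - M) * Z * gain$cfg$z_scale)
  if (gain$cond_dim > 0L) {
    if (is.null(conditioning))
      stop("model was built with conditioning; supply the conditioning matrix")
    conditioning <- as.matrix(conditioning)
    if (ncol(conditioning) != gain$cond_dim || nrow(conditioning) != nrow(Xs))
      stop("conditioning has the wrong shape")
    inp <- cbind(inp, conditioning)
  }
  if (gain$cfg$noise_dim > 0L) {
    if (is.null(noise))
      noise <- matrix(stats::rnorm(nrow(Xs) * gain$cfg$noise_dim), nrow(Xs))
    inp <- cbind(inp, noise)
  }
  inp
}

#' Impute a masked batch with a GAIN generator
#'
#' Runs the generator on the triplet (data, mask, noise-at-missing) plus
#' optional conditioning, and composes the completed matrix
#' \deqn{\hat X = M \odot X + (1-M) \odot \bar X,}
#' so observed entries are preserved exactly regardless of generator state.
#'
#' @param gain A `gain_model` (trained or untrained).
#' @param batch A `masked_batch`.
#' @param conditioning Optional conditioning matrix (rows aligned with the
#'   batch), e.g. from [pathloss_conditioning()].
#' @return List of class `imputed_batch`: `X_bar` (raw generator output,
#'   de-standardized), `X_hat` (completed matrix), `M`.
#' @export
gain_impute <- function(gain, batch, conditioning = NULL) {
  stopifnot(inherits(gain, "gain_model"), inherits(batch, "masked_batch"))
  if (ncol(batch$X) != gain$data_dim)
    stop("batch width does not match the model's data dimension")
  st <- gain$standardizer
  lv <- if (gain$cfg$center == "window") .row_level(batch$X, batch$M) else 0
  Xc <- batch$X - lv * batch$M
  Xs <- sweep(sweep(Xc, 2L, st$mu, "-"), 2L, st$sd, "/") * batch$M
  inp <- .gain_g_input(gain, Xs, batch$M, batch$Z, conditioning)
  Xbar_s <- mlp_forward(gain$G, inp)$out
  X_bar <- sweep(sweep(Xbar_s, 2L, st$sd, "*"), 2L, st$mu, "+") + lv
  X_hat <- batch$M * batch$X + (1 - batch$M) * X_bar
  structure(list(X_bar = X_bar, X_hat = X_hat, M = batch$M),
            class = "imputed_batch")
}

#' Path-loss conditioning features for the generator
#'
#' For each target location, the planar coordinates plus two outputs of the
#' log-distance path-loss model at the implied antenna distance: the
#' predicted RSSI and its local rate of change with distance
#' (`-10 n / (d ln 10)` dB/m), which summarizes how fast the signal is
#' expected to move — the quantity the differential channel tracks.
#'
#' @param model A [path_loss_model()].
#' @param positions Matrix `n x 3` of target coordinates (meters).
#' @param antenna Length-3 antenna position (meters).
#' @return Matrix `n x 4`: x, y, predicted RSSI, predicted RSSI slope.
#' @export
pathloss_conditioning <- function(model, positions, antenna) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3L, length(antenna) == 3L)
  d <- sqrt(rowSums(sweep(positions, 2L, antenna, "-")^2))
  d <- pmax(d, 1e-3)
  det <- path_loss_model(model$A, model$n, model$d0, 0)
  cbind(x = positions[, 1L], y = positions[, 2L],
        rssi = predict_rssi(det, d),
        slope = -10 * model$n / (d * log(10)))
}

#' Train a GAIN on complete data with synthetic masking
#'
#' Alternates discriminator and generator updates with the canonical GAIN
#' objectives: the discriminator minimizes masked cross-entropy between the
#' mask and its per-entry predictions on the completed matrix (given the
#' hint), and the generator minimizes the adversarial term on missing
#' entries plus `alpha` times the squared reconstruction error on observed
#' entries. Data are standardized per column internally (the standardizer
#' is stored on the model and inverted on output). A fresh Bernoulli mask
#' is drawn per minibatch. Fully seeded.
#'
#' @param complete Numeric matrix of complete training rows.
#' @param conditioning Optional conditioning matrix (same rows).
#' @param cfg A [gain_config()].
#' @param missing_rate Masking rate used during training (default 0.3).
#' @param seed Integer seed.
#' @param verbose Print losses every 20 epochs.
#' @return A trained `gain_model` with a `history` data.frame of per-epoch
#'   generator/discriminator losses.
#' @export
train_gain <- function(complete, conditioning = NULL, cfg = gain_config(),
                       missing_rate = 0.3, seed = 1, verbose = FALSE) {
  complete <- as.matrix(complete)
  if (any(is.na(complete))) stop("'complete' must have no missing entries")
  cond_dim <- if (is.null(conditioning)) 0L else ncol(as.matrix(conditioning))
  gain <- gain_new(cfg, ncol(complete), cond_dim, seed = seed)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed) + 1L)
  centred <- if (cfg$center == "window")
    complete - rowMeans(complete) else complete
  mu <- colMeans(centred)
  sd_ <- apply(centred, 2L, stats::sd)
  degenerate <- all(sd_ == 0)
  sd_[sd_ == 0] <- 1
  gain$standardizer <- list(mu = mu, sd = sd_)
  if (!is.null(conditioning)) conditioning <- as.matrix(conditioning)
  n <- nrow(complete); p <- ncol(complete)
  optG <- opt_init(gain$G$params); optD <- opt_init(gain$D$params)
  hist_list <- vector("list", cfg$epochs)
  eps <- 1e-7
  n_epochs <- if (degenerate) min(cfg$epochs, 1L) else cfg$epochs
  for (epoch in seq_len(n_epochs)) {
    idx <- sample.int(n)
    gl <- 0; dl <- 0; nb <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      bi <- idx[start:min(start + cfg$batch_size - 1L, n)]
      if (length(bi) < 2L) next
      B <- length(bi)
      Xb <- complete[bi, , drop = FALSE]
      M <- matrix(stats::rbinom(B * p, 1L, 1 - missing_rate), B)
      lv <- if (cfg$center == "window") .row_level(Xb, M) else 0
      Xs <- sweep(sweep(Xb - lv, 2L, mu, "-"), 2L, sd_, "/")
      Z <- matrix(stats::rnorm(B * p), B) * (1 - M)
      cond_b <- if (!is.null(conditioning)) conditioning[bi, , drop = FALSE]
      Bh <- matrix(stats::rbinom(B * p, 1L, cfg$hint_rate), B)
      H <- Bh * M + 0.5 * (1 - Bh)
      ginp <- .gain_g_input(gain, Xs * M, M, Z, cond_b)
      # --- discriminator step (generator detached) ---
      gfw <- mlp_forward(gain$G, ginp)
      Xhat <- M * Xs + (1 - M) * gfw$out
      dfw <- mlp_forward(gain$D, cbind(Xhat, H), keep_cache = TRUE)
      P <- pmin(pmax(dfw$out, eps), 1 - eps)
      d_loss <- -mean(M * log(P) + (1 - M) * log(1 - P))
      dP <- -(M / P - (1 - M) / (1 - P)) / length(P)
      db <- mlp_backward(gain$D, dfw$cache, dP)
      stpD <- opt_step(gain$D$params, db$grads, optD, lr = cfg$lr)
      gain$D$params <- stpD$params; optD <- stpD$state
      # --- generator step ---
      gfw <- mlp_forward(gain$G, ginp, keep_cache = TRUE)
      Xhat <- M * Xs + (1 - M) * gfw$out
      dfw <- mlp_forward(gain$D, cbind(Xhat, H), keep_cache = TRUE)
      P <- pmin(pmax(dfw$out, eps), 1 - eps)
      adv <- -mean((1 - M) * log(P))
      n_obs <- max(sum(M), 1)
      rec <- sum(M * (Xs - gfw$out)^2) / n_obs
      g_loss <- adv + cfg$alpha * rec
      if (!is.finite(g_loss) || !is.finite(d_loss))
        stop("non-finite GAIN loss at epoch ", epoch, " (diverged)")
      dP_g <- -((1 - M) / P) / length(P)
      db_g <- mlp_backward(gain$D, dfw$cache, dP_g)
      dXhat <- db_g$dX[, seq_len(p), drop = FALSE]
      dXbar <- (1 - M) * dXhat - cfg$alpha * 2 * M * (Xs - gfw$out) / n_obs
      gb <- mlp_backward(gain$G, gfw$cache, dXbar)
      stpG <- opt_step(gain$G$params, gb$grads, optG, lr = cfg$lr)
      gain$G$params <- stpG$params; optG <- stpG$state
      gl <- gl + g_loss; dl <- dl + d_loss; nb <- nb + 1L
    }
    hist_list[[epoch]] <- data.frame(epoch = epoch, g_loss = gl / max(nb, 1L),
                                     d_loss = dl / max(nb, 1L))
    if (verbose && epoch %% 20L == 0L)
      message(sprintf("epoch %4d  G %.4f  D %.4f", epoch,
                      gl / max(nb, 1L), dl / max(nb, 1L)))
  }
  gain$history <- do.call(rbind, hist_list[seq_len(n_epochs)])
  gain
}

#' Column-mean and linear-interpolation imputation baselines
#'
#' Reference imputers the GAIN is compared against. `impute_column_mean`
#' fills each missing entry with the column's observed mean.
#' `impute_linear_interp` treats each row as a time sequence and linearly
#' interpolates missing entries between observed neighbours (constant
#' extrapolation at the edges; the row's observed mean if nothing is
#' observed).
#'
#' @param X Numeric data matrix (masked entries may hold anything).
#' @param M Binary mask, 1 = observed.
#' @return Completed matrix; observed entries unchanged.
#' @export
impute_column_mean <- function(X, M) {
  X <- as.matrix(X); M <- as.matrix(M)
  out <- X
  for (j in seq_len(ncol(X))) {
    obs <- M[, j] == 1
    fill <- if (any(obs)) mean(X[obs, j]) else mean(X[M == 1])
    out[!obs, j] <- fill
  }
  out
}

#' @rdname impute_column_mean
#' @export
impute_linear_interp <- function(X, M) {
  X <- as.matrix(X); M <- as.matrix(M)
  out <- X
  for (i in seq_len(nrow(X))) {
    obs <- which(M[i, ] == 1)
    if (length(obs) == 0L) { out[i, ] <- mean(X[M == 1]); next }
    if (length(obs) == 1L) { out[i, ] <- X[i, obs]; next }
    out[i, ] <- stats::approx(obs, X[i, obs], xout = seq_len(ncol(X)),
                              rule = 2)$y
  }
  out
}

#' Held-out imputation RMSE
#'
#' RMSE restricted to the masked entries of a batch with known truth.
#'
#' @param completed Completed data matrix.
#' @param batch A `masked_batch` built by [make_masked_batch()] (has truth).
#' @return RMSE over entries with `M = 0`.
#' @export
imputation_rmse <- function(completed, batch) {
  stopifnot(inherits(batch, "masked_batch"))
  if (is.null(batch$truth)) stop("batch has no ground truth")
  miss <- batch$M == 0
  sqrt(mean((completed[miss] - batch$truth[miss])^2))
}

#' Dual-channel GAIN data matrix from RSSI windows
#'
#' Binds each RSSI window with its first-difference window into one row
#' `[rssi_1..rssi_L, diff_1..diff_{L-1}]`, the layout the generator is
#' trained on (it generates both the RSSI sequence and its differentials).
#' `gain_diff_consistency` measures, on a completed matrix, the mean
#' absolute gap between the generated differential channel and the first
#' difference of the generated RSSI channel — an internal-consistency
#' metric tracked on converged runs.
#'
#' @param rssi_windows Matrix `n x L` of RSSI windows.
#' @return `gain_dual_channel_matrix`: matrix `n x (2L - 1)`.
#' @export
gain_dual_channel_matrix <- function(rssi_windows) {
  rssi_windows <- as.matrix(rssi_windows)
  L <- ncol(rssi_windows)
  if (L < 2L) stop("windows must have length >= 2")
  cbind(rssi_windows,
        rssi_windows[, -1L, drop = FALSE] - rssi_windows[, -L, drop = FALSE])
}

#' @rdname gain_dual_channel_matrix
#' @param completed Completed dual-channel matrix (`n x (2L - 1)`).
#' @param L RSSI window length.
#' @export
gain_diff_consistency <- function(completed, L) {
  completed <- as.matrix(completed)
  if (ncol(completed) != 2L * L - 1L) stop("matrix width must be 2L - 1")
  rssi <- completed[, seq_len(L), drop = FALSE]
  dch <- completed[, L + seq_len(L - 1L), drop = FALSE]
  mean(abs((rssi[, -1L, drop = FALSE] - rssi[, -L, drop = FALSE]) - dch))
}

#' Wrap a trained GAIN as a matrix imputer
#'
#' Returns a closure mapping a matrix with `NA`s to a completed matrix,
#' suitable for [make_training_set()]'s `"impute"` mode.
#'
#' @param gain A trained `gain_model` built without conditioning.
#' @param seed Integer seed for the random matrix.
#' @return A function `matrix -> matrix`.
#' @export
gain_imputer <- function(gain, seed = 1) {
  stopifnot(inherits(gain, "gain_model"))
  force(gain); force(seed)
  function(X_na) {
    b <- masked_batch_from_na(X_na, seed = seed)
    gain_impute(gain, b)$X_hat
  }
}
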