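#' RF scene configuration for the synthetic-data generator
#'
#' Describes a simulated monitoring scene: reader antenna positions, a
#' reference-tag grid, the propagation model, the tag trajectory model,
#' and the missingness process. Defaults emulate the field deployment the
#' calibration tables come from: four antennas suspended ~2.4 m above a
#' shallow pond, reference power A = -54.42 dBm at 1 m, path-loss exponent
#' n = 1.218, and 2 dB shadow fading (independent per reading by default;
#' see `shadow_mode` for the temporally persistent variant).
#'
#' @param antennas Numeric matrix (rows = antennas, cols = x, y, z meters).
#'   Default: the three surveyed antenna positions plus a fourth completing
#'   the rectangle over the arena.
#' @param pathloss A [path_loss_model()]; default
#'   `path_loss_model(-54.42, 1.218, sigma_shadow = 2)`.
#' @param arena Length-6 numeric `c(xmin, xmax, ymin, ymax, zmin, zmax)`
#'   bounding the tag trajectory (meters).
#' @param ref_spacing Reference-tag grid spacing in meters.
#' @param step_sd Random-walk step standard deviation per timestep, meters.
#' @param sample_rate Readings per trajectory step and antenna (default 1).
#' @param missing_rate Baseline probability a reading is lost.
#' @param occlusion_zones List of axis-aligned boxes, each
#'   `c(xmin, xmax, ymin, ymax, zmin, zmax)`; a reading whose tag--antenna
#'   segment crosses a box is lost with `occlusion_dropout` instead.
#' @param occlusion_dropout Dropout probability inside occlusion (default 0.8).
#' @param shadow_mode `"iid"` (default) or `"ar1"` temporal structure of the
#'   shadow-fading term. Independent draws model fast fading; the AR(1)
#'   option models obstruction that persists across consecutive readings
#'   (used by the locator benchmark scene, where temporally structured
#'   noise is what makes the first-difference stream informative).
#' @param ar1_rho AR(1) coefficient when `shadow_mode = "ar1"` (default 0.8).
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(antennas = default_antennas(),
                         pathloss = path_loss_model(-54.42, 1.218, sigma_shadow = 2),
                         arena = c(-1.5, 1.5, -1.5, 1.5, 0, 1),
                         ref_spacing = 0.5,
                         step_sd = 0.05,
                         sample_rate = 1L,
                         missing_rate = 0,
                         occlusion_zones = list(),
                         occlusion_dropout = 0.8,
                         shadow_mode = c("iid", "ar1"),
                         ar1_rho = 0.8) {
  shadow_mode <- match.arg(shadow_mode)
  antennas <- as.matrix(antennas)
  if (nrow(antennas) < 1L || ncol(antennas) != 3L)
    stop("'antennas' must be a matrix with >= 1 row and 3 columns")
  stopifnot(inherits(pathloss, "path_loss_model"))
  if (length(arena) != 6L || any(arena[c(2, 4, 6)] <= arena[c(1, 3, 5)]))
    stop("'arena' must be c(xmin, xmax, ymin, ymax, zmin, zmax) with max > min")
  if (ref_spacing <= 0) stop("'ref_spacing' must be positive")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("'missing_rate' must be in [0, 1)")
  if (ar1_rho < 0 || ar1_rho >= 1) stop("'ar1_rho' must be in [0, 1)")
  structure(list(antennas = antennas, pathloss = pathloss, arena = arena,
                 ref_spacing = ref_spacing, step_sd = step_sd,
                 sample_rate = as.integer(sample_rate),
                 missing_rate = missing_rate,
                 occlusion_zones = occlusion_zones,
                 occlusion_dropout = occlusion_dropout,
                 shadow_mode = shadow_mode, ar1_rho = ar1_rho),
            class = "scene_config")
}

#' Default antenna layout
#'
#' The three surveyed antenna positions from the field deployment plus a
#' fourth (its coordinates were never surveyed; the default mirrors the
#' first antenna across the arena) so the scene has four channels.
#'
#' @return A 4 x 3 matrix of antenna coordinates in meters.
#' @export
default_antennas <- function() {
  m <- rbind(c(-1.2, 0.0, 2.4),
             c(0.0, 0.9, 2.3),
             c(0.0, -1.1, 2.4),
             c(1.2, 0.0, 2.4))
  rownames(m) <- c("A", "B", "C", "D")
  colnames(m) <- c("x", "y", "z")
  m
}

# does the segment p0 -> p1 intersect the axis-aligned box? (slab method)
.segment_hits_box <- function(p0, p1, box) {
  d <- p1 - p0
  t0 <- 0; t1 <- 1
  for (a in 1:3) {
    lo <- box[2 * a - 1]; hi <- box[2 * a]
    if (abs(d[a]) < 1e-12) {
      if (p0[a] < lo || p0[a] > hi) return(FALSE)
    } else {
      ta <- (lo - p0[a]) / d[a]; tb <- (hi - p0[a]) / d[a]
      if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
      t0 <- max(t0, ta); t1 <- min(t1, tb)
      if (t0 > t1) return(FALSE)
    }
  }
  TRUE
}

# reflected random walk inside the arena
.simulate_trajectory <- function(cfg, n_steps) {
  lo <- cfg$arena[c(1, 3, 5)]; hi <- cfg$arena[c(2, 4, 6)]
  pos <- matrix(NA_real_, n_steps, 3L)
  p <- (lo + hi) / 2
  for (t in seq_len(n_steps)) {
    p <- p + stats::rnorm(3L, 0, cfg$step_sd)
    for (a in 1:3) {  # reflect at the walls
      if (p[a] < lo[a]) p[a] <- 2 * lo[a] - p[a]
      if (p[a] > hi[a]) p[a] <- 2 * hi[a] - p[a]
      p[a] <- min(max(p[a], lo[a]), hi[a])
    }
    pos[t, ] <- p
  }
  colnames(pos) <- c("x", "y", "z")
  pos
}

# shadow-fading matrix (n_steps x n_antennas), stationary sd = sigma
.shadow_draws <- function(cfg, n_steps) {
  sigma <- cfg$pathloss$sigma_shadow
  H <- nrow(cfg$antennas)
  if (sigma == 0) return(matrix(0, n_steps, H))
  if (cfg$shadow_mode == "iid")
    return(matrix(stats::rnorm(n_steps * H, 0, sigma), n_steps, H))
  rho <- cfg$ar1_rho
  e <- matrix(0, n_steps, H)
  e[1L, ] <- stats::rnorm(H, 0, sigma)
  innov_sd <- sigma * sqrt(1 - rho^2)
  for (t in 2:n_steps)
    e[t, ] <- rho * e[t - 1L, ] + stats::rnorm(H, 0, innov_sd)
  e
}

#' Simulate a reader log over a random trajectory
#'
#' Walks a tag through the arena and, per timestep and antenna, draws an
#' RSSI from the scene's path-loss model plus shadow fading; each reading
#' is then lost (logged as `NA`) with the baseline `missing_rate`, raised to
#' `occlusion_dropout` when the tag--antenna segment crosses an occlusion
#' box. Fully seeded and deterministic given `seed`.
#'
#' @param cfg A [scene_config()].
#' @param n_steps Number of trajectory timesteps.
#' @param tag_id Tag identifier recorded in the log.
#' @param seed Integer seed.
#' @return A list with `log` (data.frame `timestamp, tag_id, antenna_id,
#'   rssi_dbm`, one row per step x antenna x reading, `NA` = lost) and
#'   `truth` (data.frame `timestamp, tag_id, x, y, z`).
#' @export
simulate_log <- function(cfg, n_steps, tag_id = "tag1", seed = 1) {
  stopifnot(inherits(cfg, "scene_config"))
  if (n_steps < 1L) stop("'n_steps' must be positive")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  H <- nrow(cfg$antennas)
  ant_ids <- rownames(cfg$antennas)
  if (is.null(ant_ids)) ant_ids <- paste0("ant", seq_len(H))
  pos <- .simulate_trajectory(cfg, n_steps)
  rssi_clean <- .clean_rssi(cfg, pos)          # n_steps x H deterministic part
  shadow <- .shadow_draws(cfg, n_steps)
  rssi <- rssi_clean - shadow
  ts <- .timestamps(n_steps)
  rows_t <- rep(seq_len(n_steps), each = H * cfg$sample_rate)
  rows_h <- rep(rep(seq_len(H), each = cfg$sample_rate), times = n_steps)
  # repeated reads within a step share the slow fading draw of that step
  val <- rssi[cbind(rows_t, rows_h)]
  p_drop <- rep(cfg$missing_rate, length(val))
  if (length(cfg$occlusion_zones)) {
    occ <- matrix(FALSE, n_steps, H)
    for (t in seq_len(n_steps)) for (h in seq_len(H)) {
      for (box in cfg$occlusion_zones) {
        if (.segment_hits_box(pos[t, ], cfg$antennas[h, ], box)) {
          occ[t, h] <- TRUE; break
        }
      }
    }
    p_drop[occ[cbind(rows_t, rows_h)]] <- cfg$occlusion_dropout
  }
  lost <- stats::runif(length(val)) < p_drop
  val[lost] <- NA_real_
  log <- data.frame(timestamp = ts[rows_t], tag_id = tag_id,
                    antenna_id = ant_ids[rows_h], rssi_dbm = val,
                    stringsAsFactors = FALSE)
  truth <- data.frame(timestamp = ts, tag_id = tag_id,
                      x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      stringsAsFactors = FALSE)
  list(log = log, truth = truth)
}

# deterministic path-loss RSSI for every position x antenna
.clean_rssi <- function(cfg, pos) {
  H <- nrow(cfg$antennas)
  out <- matrix(NA_real_, nrow(pos), H)
  pl <- cfg$pathloss
  det <- path_loss_model(pl$A, pl$n, pl$d0, 0)
  for (h in seq_len(H)) {
    d <- sqrt(rowSums((pos - matrix(cfg$antennas[h, ], nrow(pos), 3L,
                                    byrow = TRUE))^2))
    d <- pmax(d, 1e-3)
    out[, h] <- predict_rssi(det, d)
  }
  out
}

.timestamps <- function(n) {
  format(as.POSIXct("2026-01-01 00:00:00", tz = "UTC") + seq_len(n) - 1,
         "%Y-%m-%dT%H:%M:%SZ")
}

#' Build reference-tag fingerprints for a scene
#'
#' Lays a 3D grid of reference tags over the arena at the configured
#' spacing and simulates each tag's per-antenna fingerprint as the mean of
#' `n_avg` noisy readings (averaging damps the shadow fading, as the live
#' reference tags would be averaged in deployment).
#'
#' @param cfg A [scene_config()].
#' @param n_avg Readings averaged per fingerprint entry (default 10).
#' @param seed Integer seed.
#' @return A [reference_tag_set()].
#' @export
make_reference_fingerprints <- function(cfg, n_avg = 10, seed = 1) {
  stopifnot(inherits(cfg, "scene_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  ax <- lapply(1:3, function(a) {
    lo <- cfg$arena[2 * a - 1]; hi <- cfg$arena[2 * a]
    if (hi - lo <= cfg$ref_spacing) (lo + hi) / 2
    else seq(lo, hi, by = cfg$ref_spacing)
  })
  grid <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  if (nrow(grid) == 0L) stop("empty reference grid")
  clean <- .clean_rssi(cfg, grid)
  sigma <- cfg$pathloss$sigma_shadow
  noise <- if (sigma > 0)
    matrix(stats::rnorm(length(clean), 0, sigma / sqrt(n_avg)), nrow(clean))
  else 0
  reference_tag_set(grid, clean - noise)
}

#' Cut fixed-length training windows from a simulated scene
#'
#' Simulates a trajectory and cuts windows of `T + 1` consecutive readings
#' per antenna (non-overlapping by default, so windows are nearly
#' independent draws along the deployment; set `stride = 1` for maximally
#' overlapping windows), pairing each window with the true 3D coordinate
#' at the window end and with the first-difference window. In
#' `"clean"` mode no readings are dropped; in `"drop"` mode lost readings
#' stay `NA` (for imputation downstream); in `"impute"` mode they are
#' filled by the supplied imputer function (a matrix-in/matrix-out closure,
#' e.g. a trained GAIN wrapped by [gain_imputer()]).
#'
#' @param cfg A [scene_config()].
#' @param n_samples Number of windows.
#' @param T_win Window history length T (windows hold `T + 1` readings).
#' @param mode `"clean"`, `"drop"` or `"impute"`.
#' @param imputer Function used in `"impute"` mode.
#' @param stride Steps between consecutive window starts (default
#'   `T_win + 1`: non-overlapping).
#' @param seed Integer seed.
#' @return A list of class `sequence_dataset`: `rssi` (array
#'   `n_samples x (T+1) x H`), `diff` (array `n_samples x T x H`),
#'   `target` (`n_samples x 3` matrix), `T_win`, `n_antennas`.
#' @export
make_training_set <- function(cfg, n_samples, T_win = 16,
                              mode = c("clean", "drop", "impute"),
                              imputer = NULL, stride = T_win + 1L, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(cfg, "scene_config"))
  if (n_samples < 1L) stop("'n_samples' must be positive")
  if (stride < 1L) stop("'stride' must be >= 1")
  n_steps <- (n_samples - 1L) * stride + T_win + 1L
  cfg_sim <- cfg
  cfg_sim$sample_rate <- 1L  # one reading per step per antenna for windowing
  if (mode == "clean") {
    cfg_sim$missing_rate <- 0
    cfg_sim$occlusion_zones <- list()
  }
  sim <- simulate_log(cfg_sim, n_steps, seed = seed)
  H <- nrow(cfg$antennas)
  # reshape the long log back to a step x antenna matrix
  rssi_mat <- matrix(sim$log$rssi_dbm, ncol = H, byrow = TRUE)
  pos <- as.matrix(sim$truth[, c("x", "y", "z")])
  rssi_arr <- array(NA_real_, c(n_samples, T_win + 1L, H))
  target <- matrix(NA_real_, n_samples, 3L)
  for (i in seq_len(n_samples)) {
    s0 <- (i - 1L) * stride + 1L
    rssi_arr[i, , ] <- rssi_mat[s0:(s0 + T_win), , drop = FALSE]
    target[i, ] <- pos[s0 + T_win, ]
  }
  if (mode == "impute") {
    if (is.null(imputer)) stop("mode = 'impute' requires an 'imputer' function")
    flat <- matrix(rssi_arr, nrow = n_samples)
    flat <- imputer(flat)
    rssi_arr <- array(flat, dim(rssi_arr))
  }
  diff_arr <- rssi_arr[, -1L, , drop = FALSE] -
    rssi_arr[, -(T_win + 1L), , drop = FALSE]
  structure(list(rssi = rssi_arr, diff = diff_arr, target = target,
                 T_win = T_win, n_antennas = H),
            class = "sequence_dataset")
}

#' @export
print.sequence_dataset <- function(x, ...) {
  cat(sprintf("Sequence dataset: %d samples, window T = %d (+1), %d antennas\n",
              dim(x$rssi)[1], x$T_win, x$n_antennas))
  invisible(x)
}

#' Train/test benchmark scene
#'
#' The package's standard synthetic benchmark: the default scene (four
#' antennas, sigma = 2 dB shadow fading made AR(1)-persistent in time,
#' coefficient 0.8) with 2000 training and 500
#' test windows cut from disjoint trajectories, plus a 0.5 m reference grid
#' for the LANDMARC baseline.
#'
#' @param seed Integer seed.
#' @param n_train,n_test Window counts.
#' @param T_win Window history length.
#' @return List with `train`, `test` (sequence datasets), `refs`
#'   (a [reference_tag_set()]) and `cfg`.
#' @export
make_benchmark_scene <- function(seed = 1, n_train = 2000, n_test = 500,
                                 T_win = 16) {
  cfg <- scene_config(shadow_mode = "ar1")
  list(train = make_training_set(cfg, n_train, T_win, mode = "clean",
                                 seed = seed),
       test = make_training_set(cfg, n_test, T_win, mode = "clean",
                                seed = seed + 104729L),
       refs = make_reference_fingerprints(cfg, seed = seed + 224737L),
       cfg = cfg)
}
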