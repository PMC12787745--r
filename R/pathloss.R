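#' Log-distance path-loss model
#'
#' Constructs a log-distance path-loss model for UHF RFID propagation,
#' \deqn{PL(d) = A - 10\,n\,\log_{10}(d/d_0) - N_0,}
#' where `A` is the received power at the reference distance `d0` (dBm),
#' `n` is the path-loss exponent (2 in free space, smaller in guided or
#' reflective environments) and `N0 ~ Normal(0, sigma_shadow^2)` is a
#' zero-mean shadow-fading term on the dB scale.
#'
#' @param A Received signal strength at the reference distance, dBm.
#' @param n Path-loss exponent (> 0), dimensionless.
#' @param d0 Reference distance in meters (default 1).
#' @param sigma_shadow Standard deviation of the shadow-fading term in dB;
#'   0 gives a deterministic model.
#' @return An object of class `path_loss_model`.
#' @examples
#' m <- path_loss_model(A = -54.42, n = 1.218)
#' predict_rssi(m, 10)
#' @export
path_loss_model <- function(A, n, d0 = 1, sigma_shadow = 0) {
  stopifnot(is.numeric(A), length(A) == 1L, is.finite(A))
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n <= 0)
    stop("path-loss exponent 'n' must be a single positive number")
  if (!is.numeric(d0) || length(d0) != 1L || !is.finite(d0) || d0 <= 0)
    stop("reference distance 'd0' must be a single positive number")
  if (!is.numeric(sigma_shadow) || length(sigma_shadow) != 1L ||
      !is.finite(sigma_shadow) || sigma_shadow < 0)
    stop("'sigma_shadow' must be a single nonnegative number")
  structure(list(A = A, n = n, d0 = d0, sigma_shadow = sigma_shadow),
            class = "path_loss_model")
}

#' @export
print.path_loss_model <- function(x, ...) {
  cat("Log-distance path-loss model\n")
  cat(sprintf("  A     = %.4f dBm at d0 = %g m\n", x$A, x$d0))
  cat(sprintf("  n     = %.4f\n", x$n))
  cat(sprintf("  sigma = %.4f dB (shadow fading)\n", x$sigma_shadow))
  invisible(x)
}

#' Predict RSSI at a given distance
#'
#' Evaluates the log-distance path-loss model at distance `d`, optionally
#' adding a zero-mean Gaussian shadow-fading draw on the dB scale. The
#' deterministic part decreases strictly with distance.
#'
#' @param model A [path_loss_model()].
#' @param d Distance(s) from the antenna in meters; all > 0.
#' @param noise_seed Optional integer seed for the shadow-fading draw. When
#'   `NULL` (default) and `sigma_shadow > 0`, the current RNG stream is used;
#'   when `sigma_shadow = 0` the prediction is deterministic.
#' @return RSSI value(s) in dBm, same length as `d`.
#' @export
predict_rssi <- function(model, d, noise_seed = NULL) {
  stopifnot(inherits(model, "path_loss_model"))
  if (!is.numeric(d) || any(!is.finite(d)) || any(d <= 0))
    stop("distances 'd' must be positive and finite")
  rssi <- model$A - 10 * model$n * log10(d / model$d0)
  if (model$sigma_shadow > 0) {
    if (!is.null(noise_seed)) {
      old <- .save_rng()
      on.exit(.restore_rng(old))
      set.seed(as.integer(noise_seed))
    }
    rssi <- rssi - stats::rnorm(length(d), 0, model$sigma_shadow)
  }
  rssi
}

#' Convert RSSI to distance
#'
#' Inverts the deterministic part of the log-distance model:
#' \deqn{d = d_0 \cdot 10^{(A - RSSI)/(10 n)}.}
#' The map is strictly decreasing in RSSI; every real RSSI is valid.
#'
#' @param model A [path_loss_model()].
#' @param rssi RSSI value(s) in dBm.
#' @return Distance(s) in meters.
#' @export
rssi_to_distance <- function(model, rssi) {
  stopifnot(inherits(model, "path_loss_model"))
  if (!is.numeric(rssi) || any(!is.finite(rssi)))
    stop("'rssi' must be finite numeric")
  model$d0 * 10^((model$A - rssi) / (10 * model$n))
}

#' Calibrate the reference power A
#'
#' Estimates `A`, the expected RSSI at the reference distance, as the
#' arithmetic mean of repeated readings taken with the tag at `d0`
#' (conventionally 1 m) from each antenna. Returned at full precision;
#' rounding to two decimals is a presentation concern.
#'
#' @param readings_at_d0 Numeric vector of RSSI readings (dBm) at the
#'   reference distance. `NA` entries (missing readings) are dropped.
#' @return Calibrated `A` in dBm.
#' @export
calibrate_A <- function(readings_at_d0) {
  if (!is.numeric(readings_at_d0)) stop("'readings_at_d0' must be numeric")
  x <- readings_at_d0[!is.na(readings_at_d0)]
  if (length(x) == 0L) stop("no valid readings supplied")
  mean(x)
}

#' Calibrate the path-loss exponent n
#'
#' Estimates the path-loss exponent from (RSSI, distance) calibration pairs
#' measured at known tag--antenna distances. Each pair yields a per-pair
#' exponent
#' \deqn{n_i = (A - RSSI_i) / (10 \log_{10}(d_i/d_0)),}
#' and the calibrated exponent is their arithmetic mean. Per-pair values may
#' be negative when a measurement is anomalously strong; by default such
#' outliers are retained in the average (the plain inversion of the model).
#' `robust = "drop_negative"` drops them; `robust = "ols"` instead fits
#' `A - rssi ~ 10 log10(d/d0)` by least squares through the origin.
#'
#' @param A Calibrated reference power in dBm (see [calibrate_A()]).
#' @param rssi Numeric vector of measured RSSI, dBm. `NA` = missing.
#' @param distance Numeric vector of measured distances, meters.
#' @param d0 Reference distance, meters (default 1).
#' @param robust One of `"none"` (default), `"drop_negative"`, `"ols"`.
#' @return Calibrated exponent (scalar).
#' @export
calibrate_n <- function(A, rssi, distance, d0 = 1, robust = c("none", "drop_negative", "ols")) {
  robust <- match.arg(robust)
  stopifnot(is.numeric(A), length(A) == 1L)
  if (length(rssi) != length(distance))
    stop("'rssi' and 'distance' must have the same length")
  ok <- !is.na(rssi) & !is.na(distance)
  rssi <- rssi[ok]; distance <- distance[ok]
  if (any(distance <= 0)) stop("distances must be positive")
  at_ref <- abs(distance - d0) < .Machine$double.eps^0.5
  if (any(at_ref)) {
    warning(sum(at_ref), " pair(s) at the reference distance excluded (log term is zero)")
    rssi <- rssi[!at_ref]; distance <- distance[!at_ref]
  }
  if (length(rssi) == 0L) stop("no valid calibration pairs")
  lg <- 10 * log10(distance / d0)
  if (robust == "ols") return(sum(lg * (A - rssi)) / sum(lg^2))
  ni <- (A - rssi) / lg
  if (robust == "drop_negative") {
    ni <- ni[ni > 0]
    if (length(ni) == 0L) stop("no positive per-pair exponents")
  }
  mean(ni)
}

#' Read calibration pairs from CSV
#'
#' Reads a calibration-pair table with columns `coordinate_id, antenna_id,
#' rssi_dbm, distance_m`. Empty cells are parsed as missing (`NA`) and are
#' excluded by [calibrate_n()].
#'
#' @param path Path to the CSV file.
#' @return A data.frame with one row per (coordinate, antenna) cell.
#' @export
read_calibration_pairs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(NA, NA, "numeric", "numeric"))
  need <- c("coordinate_id", "antenna_id", "rssi_dbm", "distance_m")
  if (!all(need %in% names(df)))
    stop("calibration CSV must have columns: ", paste(need, collapse = ", "))
  df
}

#' Serialize / deserialize a path-loss model as JSON
#'
#' @param model A [path_loss_model()].
#' @param path Output (or input) file path.
#' @return `write_path_loss_model` invisibly returns `path`;
#'   `read_path_loss_model` returns the model.
#' @export
write_path_loss_model <- function(model, path) {
  stopifnot(inherits(model, "path_loss_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_path_loss_model
#' @export
read_path_loss_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  path_loss_model(A = x$A, n = x$n, d0 = x$d0, sigma_shadow = x$sigma_shadow)
}

# RNG bookkeeping so seeded draws do not disturb the caller's stream
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
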