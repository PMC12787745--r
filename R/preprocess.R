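#' Trim the extremes of an RSSI window
#'
#' Removes exactly one instance of the maximum and one instance of the
#' minimum from a window of RSSI readings, preserving the order of the
#' survivors. With ties, only a single copy of each extreme is removed.
#'
#' @param values Numeric vector of RSSI readings (dBm), length >= 3.
#' @return Numeric vector of length `length(values) - 2`.
#' @export
trim_extremes <- function(values) {
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("'values' must be finite numeric")
  if (length(values) < 3L) stop("need at least 3 readings to trim extremes")
  i_max <- which.max(values)
  i_min <- which.min(values[-i_max])
  # index back into the original vector
  idx <- seq_along(values)[-i_max]
  values[-c(i_max, idx[i_min])]
}

#' Asymmetric sigma filter for RSSI readings
#'
#' Obstruction weakens the signal, so low outliers are more suspect than
#' high ones: readings outside the open band `(u - 0.5*sigma, u + sigma)`
#' are excluded, where `u` and `sigma` are the mean and sample standard
#' deviation of the input. The band is deliberately tighter below the mean.
#' A zero-variance input is returned unchanged (a constant window carries
#' perfect information, and the literal open band would be empty).
#'
#' @param values Numeric vector of RSSI readings (dBm), length >= 2.
#' @return The surviving readings, order preserved.
#' @export
sigma_filter <- function(values) {
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("'values' must be finite numeric")
  if (length(values) < 2L) stop("need at least 2 readings for the sigma filter")
  u <- mean(values)
  s <- stats::sd(values)
  if (s == 0) return(values)
  values[values > u - 0.5 * s & values < u + s]
}

#' Zero-correlation correction
#'
#' When a reference tag's proximity score to the target comes out exactly
#' zero (which would otherwise give it infinite weight downstream), it is
#' replaced by `(2/3) * E_m`, where `E_m` is the smallest non-zero score in
#' the selected set. Non-zero scores are unchanged.
#'
#' @param values Numeric vector of nonnegative proximity/correlation scores
#'   for the `p > 0` selected reference tags.
#' @return The corrected vector.
#' @export
correlation_correct <- function(values) {
  if (!is.numeric(values) || length(values) == 0L || any(!is.finite(values)))
    stop("'values' must be a nonempty finite numeric vector")
  nz <- values[values != 0]
  if (length(nz) == 0L)
    stop("all scores are zero; the least non-zero score is undefined")
  e_m <- min(abs(nz))
  values[values == 0] <- (2 / 3) * e_m
  values
}

#' Build a fingerprint table from a reading log
#'
#' Groups a reading log by (tag, antenna), chunks each group's readings into
#' consecutive windows of `window_size`, and per window applies
#' [trim_extremes()] then [sigma_filter()] and averages the survivors into
#' one fingerprint value. Missing readings (`NA` RSSI) are dropped before
#' windowing; incomplete trailing windows are dropped with a warning.
#'
#' @param log A reading-log data.frame with columns
#'   `timestamp, tag_id, antenna_id, rssi_dbm` (see [read_reading_log()]).
#' @param window_size Readings per window (default 10).
#' @return A data.frame `tag_id, antenna_id, window_index, rssi_dbm, n_kept`
#'   with one row per complete window; attribute `n_discarded` counts
#'   readings removed by trimming/filtering.
#' @export
build_fingerprint <- function(log, window_size = 10) {
  stopifnot(is.data.frame(log))
  need <- c("tag_id", "antenna_id", "rssi_dbm")
  if (!all(need %in% names(log)))
    stop("log must have columns: ", paste(need, collapse = ", "))
  if (window_size < 3L) stop("'window_size' must be at least 3")
  log <- log[!is.na(log$rssi_dbm), , drop = FALSE]
  groups <- split(log, list(log$tag_id, log$antenna_id), drop = TRUE)
  out <- list(); discarded <- 0L; trailing <- 0L
  for (g in groups) {
    v <- g$rssi_dbm
    n_win <- length(v) %/% window_size
    trailing <- trailing + length(v) %% window_size
    if (n_win == 0L) next
    rows <- lapply(seq_len(n_win), function(w) {
      win <- v[((w - 1L) * window_size + 1L):(w * window_size)]
      kept <- sigma_filter(trim_extremes(win))
      discarded <<- discarded + (length(win) - length(kept))
      data.frame(tag_id = g$tag_id[1L], antenna_id = g$antenna_id[1L],
                 window_index = w, rssi_dbm = mean(kept),
                 n_kept = length(kept), stringsAsFactors = FALSE)
    })
    out[[length(out) + 1L]] <- do.call(rbind, rows)
  }
  if (trailing > 0L)
    warning(trailing, " trailing reading(s) in incomplete windows dropped")
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(tag_id = character(), antenna_id = character(),
               window_index = integer(), rssi_dbm = numeric(),
               n_kept = integer(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "n_discarded") <- discarded
  res
}
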