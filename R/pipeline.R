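#' Read and write reader logs
#'
#' Reader logs are CSV with columns `timestamp, tag_id, antenna_id,
#' rssi_dbm`; empty cells or `"--"` denote lost readings and parse to `NA`.
#' Malformed rows (wrong field count, unparseable RSSI) are collected and
#' reported with their line numbers; if more than 10% of rows are
#' malformed the read aborts.
#'
#' @param path CSV file path.
#' @return A data.frame reading log; attribute `malformed` lists skipped
#'   line numbers.
#' @export
read_reading_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA", "--"))
  need <- c("timestamp", "tag_id", "antenna_id", "rssi_dbm")
  if (!all(need %in% names(df)))
    stop("reading log must have columns: ", paste(need, collapse = ", "))
  raw <- df$rssi_dbm
  if (!is.numeric(raw)) {
    parsed <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(parsed))
    if (length(bad) > 0.1 * nrow(df))
      stop("more than 10% malformed rows in ", path,
           " (first bad lines: ", paste(utils::head(bad + 1L, 5), collapse = ", "), ")")
    if (length(bad))
      warning(length(bad), " malformed RSSI value(s) set to missing (lines ",
              paste(utils::head(bad + 1L, 10), collapse = ", "), ")")
    df$rssi_dbm <- parsed
  }
  attr(df, "malformed") <- if (is.numeric(raw)) integer() else bad + 1L
  df
}

#' @rdname read_reading_log
#' @param log A reading-log data.frame.
#' @export
write_reading_log <- function(log, path) {
  out <- log
  out$rssi_dbm <- ifelse(is.na(out$rssi_dbm), "",
                         format(out$rssi_dbm, trim = TRUE, digits = 15))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write and read estimated positions
#'
#' Positions CSV: `timestamp, tag_id, x, y, z`, coordinates in meters
#' written with 3 decimals.
#'
#' @param estimates Data.frame with columns `timestamp, tag_id, x, y, z`.
#' @param path Output CSV path.
#' @export
write_positions <- function(estimates, path) {
  need <- c("timestamp", "tag_id", "x", "y", "z")
  if (!all(need %in% names(estimates)))
    stop("estimates must have columns: ", paste(need, collapse = ", "))
  out <- estimates[, need]
  for (a in c("x", "y", "z")) out[[a]] <- sprintf("%.3f", out[[a]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_positions
#' @export
read_positions <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c("character", "character", "numeric",
                                 "numeric", "numeric"))
}

#' Run the localization pipeline end to end
#'
#' Executes the enabled stages in order on a simulated scene:
#' `simulate` (reader log + truth), `filter` (fingerprint construction),
#' `locate` (LANDMARC weighted kNN per fingerprint window), `evaluate`
#' (error report against the truth). Artifacts are written under `outdir`
#' and a JSON report with the seed, a config hash and per-stage timings is
#' returned (and written) at the end. Rerunning with the same config and
#' seed reproduces the report metrics exactly.
#'
#' @param config A list (or path to a YAML file) with optional fields
#'   `seed`, `n_steps`, `window`, `k`, `stages` (subset of
#'   `c("simulate", "filter", "locate", "evaluate")`), and `scene`
#'   overrides (`missing_rate`, `ref_spacing`, `step_sd`).
#' @param outdir Output directory (created if absent).
#' @return The report, invisibly; also written to `outdir/report.json`.
#' @export
run_pipeline <- function(config = list(), outdir = tempfile("taglocrun")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  n_steps <- config$n_steps %||% 200L
  window <- config$window %||% 10L
  k <- config$k %||% 4L
  stages <- config$stages %||% c("simulate", "filter", "locate", "evaluate")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- scene_config(missing_rate = config$scene$missing_rate %||% 0,
                      ref_spacing = config$scene$ref_spacing %||% 0.5,
                      step_sd = config$scene$step_sd %||% 0.05)
  report <- list(seed = seed,
                 config_hash = .config_hash(config),
                 stages = stages, timing = list())
  tic <- function(expr, name) {
    t0 <- proc.time()[["elapsed"]]
    res <- expr
    report$timing[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  sim <- NULL; fp <- NULL; est <- NULL
  if ("simulate" %in% stages) {
    sim <- tic(simulate_log(cfg, n_steps, seed = seed), "simulate")
    write_reading_log(sim$log, file.path(outdir, "readings.csv"))
    utils::write.csv(sim$truth, file.path(outdir, "truth.csv"),
                     row.names = FALSE, quote = FALSE)
  } else stop("pipeline currently requires the 'simulate' stage as source")
  if ("filter" %in% stages) {
    fp <- tic(suppressWarnings(build_fingerprint(sim$log, window)), "filter")
    utils::write.csv(fp, file.path(outdir, "fingerprints.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  if ("locate" %in% stages) {
    if (is.null(fp)) stop("'locate' requires the 'filter' stage")
    est <- tic({
      refs <- make_reference_fingerprints(cfg, seed = seed + 1L)
      ants <- sort(unique(fp$antenna_id))
      wins <- sort(unique(fp$window_index))
      rows <- lapply(wins, function(w) {
        target <- vapply(ants, function(a) {
          v <- fp$rssi_dbm[fp$antenna_id == a & fp$window_index == w]
          if (length(v)) v[1L] else NA_real_
        }, numeric(1))
        p <- estimate_position(target, refs, knn_config(k = k))
        step_end <- min(w * window, nrow(sim$truth))
        data.frame(timestamp = sim$truth$timestamp[step_end],
                   tag_id = sim$truth$tag_id[1L],
                   x = p[1L], y = p[2L], z = p[3L],
                   truth_x = sim$truth$x[step_end],
                   truth_y = sim$truth$y[step_end],
                   truth_z = sim$truth$z[step_end],
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    }, "locate")
    write_positions(est, file.path(outdir, "positions.csv"))
  }
  if ("evaluate" %in% stages) {
    if (is.null(est)) stop("'evaluate' requires the 'locate' stage")
    ev <- tic(evaluate_positions(
      as.matrix(est[, c("truth_x", "truth_y", "truth_z")]),
      as.matrix(est[, c("x", "y", "z")])), "evaluate")
    report$metrics <- list(
      n = ev$summary$n, mean_error_m = ev$summary$mean,
      sd_error_m = ev$summary$sd, median_error_m = ev$summary$median,
      min_error_m = ev$summary$min, max_error_m = ev$summary$max,
      rmse_m = ev$summary$rmse,
      per_axis_rel_pct = as.list(ev$per_axis_rel))
  }
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

.config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  # small rolling hash; avoids a digest dependency
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}
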