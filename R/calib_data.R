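#' Bundled field measurement tables
#'
#' The package ships the measurement tables from a field deployment of the
#' localization system over giant-salamander breeding ponds (four reader
#' antennas suspended about 2.4 m above the water):
#'
#' * `tagloc_calib_1m()` — 36 RSSI readings (12 per antenna for antennas
#'   A, B, C) with the tag held 1 m from each antenna; the input for
#'   calibrating the reference power `A`.
#' * `tagloc_calib_pairs()` — RSSI and measured tag--antenna distance for
#'   five test coordinates against each antenna; cells the reader could not
#'   observe are missing (`NA`). The input for calibrating the path-loss
#'   exponent `n`.
#' * `tagloc_benchmark_positions()` — ten ground-truth target coordinates
#'   and the 3D positions estimated for them by five sequence models
#'   (`dtr`, `str`, `tcn`, `gru`, `lstm`), long format.
#' * `tagloc_ablation_summary()` — error summary statistics (mean, SD, max,
#'   min, meters) for four pipeline variants toggling the LANDMARC baseline,
#'   GAIN imputation and the dual-stream transformer.
#'
#' @return A data.frame (see above for each table's columns).
#' @name field_tables
NULL

.extdata <- function(file) {
  p <- system.file("extdata", file, package = "tagloc3d")
  if (p == "") stop("bundled file not found: ", file)
  p
}

#' @rdname field_tables
#' @export
tagloc_calib_1m <- function() {
  utils::read.csv(.extdata("calib_rssi_1m.csv"), stringsAsFactors = FALSE)
}

#' @rdname field_tables
#' @export
tagloc_calib_pairs <- function() {
  read_calibration_pairs(.extdata("calib_pairs.csv"))
}

#' @rdname field_tables
#' @export
tagloc_benchmark_positions <- function() {
  utils::read.csv(.extdata("benchmark_positions.csv"), stringsAsFactors = FALSE)
}

#' @rdname field_tables
#' @export
tagloc_ablation_summary <- function() {
  utils::read.csv(.extdata("ablation_summary.csv"), stringsAsFactors = FALSE)
}
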