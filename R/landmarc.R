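#' Reference tag set for LANDMARC positioning
#'
#' Couples the known 3D positions of reference tags with their per-antenna
#' RSSI fingerprints. Missing fingerprint entries (`NA`) are allowed; the
#' RSSI-space distance restricts itself to antennas observed in both the
#' target and the reference tag.
#'
#' @param positions Numeric matrix, one row per reference tag, columns
#'   x, y, z (meters).
#' @param fingerprints Numeric matrix, one row per reference tag, one column
#'   per antenna (RSSI dBm, `NA` = missing).
#' @return An object of class `reference_tag_set`.
#' @export
reference_tag_set <- function(positions, fingerprints) {
  positions <- as.matrix(positions); fingerprints <- as.matrix(fingerprints)
  if (ncol(positions) != 3L) stop("'positions' must have 3 columns (x, y, z)")
  if (nrow(positions) != nrow(fingerprints))
    stop("'positions' and 'fingerprints' must have the same number of rows")
  if (any(!is.finite(positions))) stop("reference positions must be finite")
  structure(list(positions = positions, fingerprints = fingerprints),
            class = "reference_tag_set")
}

#' @export
print.reference_tag_set <- function(x, ...) {
  cat(sprintf("Reference tag set: %d tags, %d antennas\n",
              nrow(x$positions), ncol(x$fingerprints)))
  invisible(x)
}

#' RSSI-space distance between a target and a reference fingerprint
#'
#' Euclidean distance over the antennas observed in both vectors:
#' \deqn{E_j = \sqrt{\sum_h (RSSI_{target,h} - RSSI_{ref_j,h})^2}.}
#' Returns `NA` when no antenna is shared (the tag is unusable).
#'
#' @param target Numeric RSSI vector of the target tag (`NA` = missing).
#' @param ref Numeric RSSI vector of a reference tag, same length.
#' @return Nonnegative score, or `NA` if no shared antennas.
#' @export
rssi_space_distance <- function(target, ref) {
  if (length(target) != length(ref))
    stop("'target' and 'ref' must have equal length")
  shared <- !is.na(target) & !is.na(ref)
  if (!any(shared)) return(NA_real_)
  sqrt(sum((target[shared] - ref[shared])^2))
}

#' kNN configuration for LANDMARC
#'
#' @param k Number of nearest reference tags (default 4, common LANDMARC
#'   practice).
#' @param epsilon Small positive stabilizer added to squared RSSI-space
#'   distances so an exact fingerprint match gets a large finite weight.
#' @return An object of class `knn_config`.
#' @export
knn_config <- function(k = 4, epsilon = 1e-6) {
  if (k < 1) stop("'k' must be at least 1")
  if (epsilon <= 0) stop("'epsilon' must be positive")
  structure(list(k = as.integer(k), epsilon = epsilon), class = "knn_config")
}

#' Estimate a 3D position by LANDMARC weighted kNN
#'
#' Computes RSSI-space distances `E_j` from the target fingerprint to every
#' usable reference tag, selects the `k` smallest (ties broken by reference
#' index, stable), and returns the weighted centroid of their positions with
#' weights
#' \deqn{w_j = \frac{1/(E_j^2+\epsilon)}{\sum_i 1/(E_i^2+\epsilon)}.}
#' The weights sum to one and the estimate lies in the convex hull of the
#' selected reference positions.
#'
#' @param target Numeric RSSI vector for the target tag (`NA` = missing).
#' @param refs A [reference_tag_set()].
#' @param cfg A [knn_config()].
#' @return Numeric length-3 vector (x, y, z) with attributes `neighbors`
#'   (selected reference indices) and `weights`.
#' @export
estimate_position <- function(target, refs, cfg = knn_config()) {
  stopifnot(inherits(refs, "reference_tag_set"), inherits(cfg, "knn_config"))
  if (length(target) != ncol(refs$fingerprints))
    stop("target fingerprint length must equal the antenna count")
  e <- apply(refs$fingerprints, 1L, rssi_space_distance, target = target)
  usable <- which(!is.na(e))
  if (length(usable) < length(e))
    warning(length(e) - length(usable),
            " reference tag(s) share no antenna with the target; excluded")
  if (length(usable) < cfg$k)
    stop("fewer than k = ", cfg$k, " usable reference tags")
  ord <- usable[order(e[usable], usable)]  # stable: index breaks ties
  sel <- ord[seq_len(cfg$k)]
  w <- 1 / (e[sel]^2 + cfg$epsilon)
  w <- w / sum(w)
  est <- as.numeric(crossprod(w, refs$positions[sel, , drop = FALSE]))
  names(est) <- c("x", "y", "z")
  attr(est, "neighbors") <- sel
  attr(est, "weights") <- w
  est
}

#' Read a reference-tag CSV
#'
#' Schema: `ref_id, x, y, z, rssi_ant1..rssi_antH` with empty cells parsed
#' as missing fingerprints.
#'
#' @param path Path to the CSV file.
#' @return A [reference_tag_set()].
#' @export
read_reference_tags <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ref_id", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("reference CSV must start with columns: ", paste(need, collapse = ", "))
  fp_cols <- setdiff(names(df), need)
  if (length(fp_cols) == 0L) stop("reference CSV has no fingerprint columns")
  reference_tag_set(as.matrix(df[, c("x", "y", "z")]),
                    as.matrix(df[, fp_cols, drop = FALSE]))
}
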