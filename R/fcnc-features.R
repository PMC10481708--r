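#' Extract functional connectivity neural circuits at a threshold
#'
#' A functional connectivity neural circuit (FCNC) is a 1-dimensional cycle of
#' the Vietoris-Rips complex, localized by the representative cycle its
#' persistence class was born with. The FCNC set at threshold `delta` is
#' cumulative in births: every dim-1 interval with `birth <= delta` counts,
#' whether or not the loop has been filled by `delta`. This makes per-region
#' counts non-decreasing in the threshold, the signature pattern of circuit
#' counts in correlation networks.
#'
#' By default, bars of zero persistence are skipped: a cycle-closing edge that
#' is simultaneously the longest edge of a triangle is filled at its own birth
#' value, and in dense correlation graphs such instantly-filled cycles vastly
#' outnumber genuine circuits. Set `include_zero = TRUE` to count every
#' recorded interval.
#'
#' @param barcode A [reduce_boundary_matrix()] result.
#' @param delta Threshold in `[0, t_max]`.
#' @param scan_id Identifier attached to the records.
#' @param include_zero Count zero-persistence bars too? Default `FALSE`.
#' @return Data frame of class `fcnc_records` with columns `scan_id`,
#'   `threshold`, `cycle_id`, `birth`, `death`, `length` (number of edges in
#'   the representative) and a list column `members` (sorted region indices
#'   appearing in the representative).
#' @export
extract_fcnc <- function(barcode, delta, scan_id = "scan", include_zero = FALSE) {
  stopifnot(inherits(barcode, "barcode"))
  if (delta < 0 || delta > barcode$config$t_max)
    stop("delta must lie in [0, t_max]")
  iv <- barcode$intervals
  keep <- which(iv$dim == 1L & iv$birth <= delta &
                  (include_zero | iv$death > iv$birth))
  reps <- barcode$representatives[keep]
  out <- data.frame(
    scan_id = rep(as.character(scan_id), length(keep)),
    threshold = rep(delta, length(keep)),
    cycle_id = seq_along(keep),
    birth = iv$birth[keep],
    death = iv$death[keep],
    length = vapply(reps, nrow, integer(1)))
  out$members <- lapply(reps, function(m) sort(unique(as.integer(m))))
  class(out) <- c("fcnc_records", "data.frame")
  out
}

#' Per-region circuit involvement counts
#'
#' For one scan/threshold batch of records, counts for each region the number
#' of circuits whose representative touches it.
#'
#' @param records An [extract_fcnc()] result.
#' @param n_regions Total number of regions.
#' @return Integer vector of length `n_regions` (region `r`'s count at index
#'   `r`).
#' @export
region_counts <- function(records, n_regions) {
  n_regions <- as.integer(n_regions)
  members <- unlist(records$members)
  if (length(members) && (min(members) < 1L || max(members) > n_regions))
    stop("representative region index out of range 1..", n_regions)
  counts <- integer(n_regions)
  if (length(members)) {
    # each circuit contributes at most once per region (members are unique)
    tab <- tabulate(members, nbins = n_regions)
    counts <- tab
  }
  counts
}

#' Count circuits of a given length
#'
#' @param records An [extract_fcnc()] result.
#' @param length Circuit length (number of representative edges), `>= 3`.
#' @return Integer count of records with exactly that length.
#' @export
count_by_length <- function(records, length) {
  if (length < 3L) stop("a 1-cycle has at least 3 edges")
  sum(records$length == length)
}

#' Assemble the per-scan FCNC feature table
#'
#' Long-format table feeding the two-group comparison: for every scan and
#' threshold, one row per region (circuit-involvement count) and one row per
#' requested circuit length (count of circuits of exactly that length).
#'
#' @param barcodes List of [reduce_boundary_matrix()] results, one per scan.
#' @param scan_ids Unique scan identifiers (parallel to `barcodes`).
#' @param groups Group label per scan.
#' @param thresholds Thresholds, all within `[0, t_max]`.
#' @param lengths Circuit lengths to count (default 8, a "medium" circuit on
#'   90-region networks).
#' @param include_zero Passed to [extract_fcnc()].
#' @return Data frame with columns `scan_id`, `group`, `threshold`,
#'   `feature_type` (`"region"` or `"length"`), `feature` (region label or
#'   length), `count`.
#' @export
per_scan_feature_table <- function(barcodes, scan_ids, groups,
                                   thresholds = c(0.7, 0.8, 0.9),
                                   lengths = 8L, include_zero = FALSE) {
  stopifnot(length(barcodes) == length(scan_ids),
            length(barcodes) == length(groups))
  if (anyDuplicated(scan_ids))
    stop("duplicate scan ids: ",
         paste(unique(scan_ids[duplicated(scan_ids)]), collapse = ", "))
  t_max <- barcodes[[1L]]$config$t_max
  if (any(thresholds < 0 | thresholds > t_max))
    stop("thresholds must lie in [0, t_max]")
  n_regions <- barcodes[[1L]]$n_vertices
  labels <- barcodes[[1L]]$region_labels

  rows <- vector("list", length(barcodes) * length(thresholds))
  k <- 0L
  for (s in seq_along(barcodes)) {
    for (th in thresholds) {
      rec <- extract_fcnc(barcodes[[s]], th, scan_ids[s],
                          include_zero = include_zero)
      rc <- region_counts(rec, n_regions)
      lc <- vapply(lengths, function(l) count_by_length(rec, l), integer(1))
      k <- k + 1L
      rows[[k]] <- data.frame(
        scan_id = as.character(scan_ids[s]),
        group = as.character(groups[s]),
        threshold = th,
        feature_type = c(rep("region", n_regions), rep("length", length(lengths))),
        feature = c(labels, as.character(lengths)),
        count = c(rc, lc))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
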