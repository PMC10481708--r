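#' Write/read a labelled square matrix as delimited text
#'
#' Tab-delimited with region labels as both header row and first column.
#'
#' @param m Square matrix with dimnames.
#' @param path File path.
#' @return `path` (write) or the matrix (read), invisibly for write.
#' @export
write_labeled_matrix <- function(m, path) {
  write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_labeled_matrix
#' @export
read_labeled_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                   check.names = FALSE)
  as.matrix(df)
}

read_scan_file <- function(path) {
  df <- tryCatch(
    read.table(path, header = TRUE, sep = "\t", check.names = FALSE),
    error = function(e) stop("malformed scan file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  bad <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(bad))
    stop("malformed scan file '", path, "': non-numeric cells in column(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  as.matrix(df)
}

#' Read a manifest of scans
#'
#' The manifest is tab-delimited with header columns `scan_id`, `group`,
#' `path` (scan files relative to the manifest's directory, as written by
#' [write_scans()]). All scans must share one region label set; columns are
#' reordered to the first scan's label order, so shuffled columns with
#' matching labels are harmless. Exactly two groups are required.
#'
#' @param path Manifest file path.
#' @return List with `scans` (list of [roi_timeseries()]) and `groups`
#'   (character vector parallel to `scans`).
#' @export
read_timeseries_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  need <- c("scan_id", "group", "path")
  if (!all(need %in% names(man)))
    stop("manifest '", path, "' must have columns: ",
         paste(need, collapse = ", "))
  groups <- unique(man$group)
  if (length(groups) != 2L)
    stop("manifest must contain exactly 2 groups, found ", length(groups),
         ": ", paste(groups, collapse = ", "))
  base <- dirname(path)
  canonical <- NULL
  scans <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    f <- file.path(base, man$path[i])
    values <- read_scan_file(f)
    if (is.null(canonical)) canonical <- colnames(values)
    if (!setequal(colnames(values), canonical))
      stop("scan file '", f, "': region labels do not match the first scan's")
    values <- values[, canonical, drop = FALSE]
    scans[[i]] <- roi_timeseries(values, canonical, man$scan_id[i])
  }
  list(scans = scans, groups = as.character(man$group))
}

read_distance_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  need <- c("scan_id", "group", "path")
  if (!all(need %in% names(man)))
    stop("manifest '", path, "' must have columns: ",
         paste(need, collapse = ", "))
  base <- dirname(path)
  dmats <- lapply(seq_len(nrow(man)), function(i) {
    distance_matrix(read_labeled_matrix(file.path(base, man$path[i])))
  })
  list(dmats = dmats, scan_ids = as.character(man$scan_id),
       groups = as.character(man$group))
}

#' Pipeline run settings
#'
#' @param input `"synthetic"` (simulate scans from `sim`), `"files"` (ROI
#'   time-series manifest) or `"distance"` (manifest of precomputed distance
#'   matrices — bypasses the connectivity stage, used for geometric fixtures).
#' @param sim A [simulation_config()] (required for synthetic input).
#' @param manifest Manifest path (required for file/distance input).
#' @param filtration A [filtration_config()].
#' @param thresholds FCNC thresholds within `(0, t_max]` (default 0.7, 0.8,
#'   0.9).
#' @param medium_lengths Circuit lengths to count (default 8).
#' @param alpha Significance level (default 0.05).
#' @param fdr_scope Passed to [compare_groups()].
#' @param out_dir Output directory.
#' @param seed Integer seed governing all randomness of the run (overrides
#'   the simulation config's seed so one knob reproduces a run).
#' @param include_zero Count zero-persistence bars as circuits (default
#'   `FALSE`).
#' @param write_per_scan Write per-scan correlation/distance/barcode files
#'   (default `TRUE`).
#' @return An object of class `run_config`.
#' @export
run_config <- function(input = c("synthetic", "files", "distance"),
                       sim = NULL, manifest = NULL,
                       filtration = filtration_config(),
                       thresholds = c(0.7, 0.8, 0.9),
                       medium_lengths = 8L, alpha = 0.05,
                       fdr_scope = "within_feature",
                       out_dir, seed = NULL, include_zero = FALSE,
                       write_per_scan = TRUE) {
  input <- match.arg(input)
  if (input == "synthetic" && !inherits(sim, "simulation_config"))
    stop("synthetic input requires a simulation_config in `sim`")
  if (input != "synthetic" && is.null(manifest))
    stop("file/distance input requires a manifest path")
  stopifnot(inherits(filtration, "filtration_config"))
  if (any(thresholds <= 0 | thresholds > filtration$t_max))
    stop("thresholds must lie in (0, t_max]")
  if (is.null(seed)) seed <- if (!is.null(sim)) sim$seed else 1L
  structure(
    list(input = input, sim = sim, manifest = manifest,
         filtration = filtration, thresholds = thresholds,
         medium_lengths = as.integer(medium_lengths), alpha = alpha,
         fdr_scope = fdr_scope, out_dir = out_dir, seed = as.integer(seed),
         include_zero = include_zero, write_per_scan = write_per_scan),
    class = "run_config")
}

#' Run the full topological connectivity pipeline
#'
#' Orchestrates simulate/load -> Pearson connectivity -> distance ->
#' Vietoris-Rips filtration -> persistence barcodes -> FCNC features ->
#' two-group statistics, writing a deterministic artifact layout under
#' `config$out_dir`:
#' \itemize{
#'   \item `scans/<id>_r.tsv`, `scans/<id>_d.tsv`, `scans/<id>_barcode.tsv`
#'     per scan (when `write_per_scan`),
#'   \item `betti_curves.tsv` (per-group mean Betti curves on the grid),
#'   \item `ks_tests.tsv` (Kolmogorov-Smirnov comparison of the curves),
#'   \item `features.tsv` + `features_schema.txt` (per-scan FCNC features),
#'   \item `comparison.tsv` (Mann-Whitney + FDR table),
#'   \item `length_quartiles.tsv` (box-plot numbers for length features),
#'   \item `summary.json` (machine-readable run record).
#' }
#' Statistics are skipped (with a note in the summary) when the input has
#' fewer than two groups of at least two scans, as in single-fixture runs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `summary`, `comparison`, `ks`, `features`,
#'   `curves` (per-scan Betti curves) and `barcodes`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  scan_dir <- file.path(out, "scans")
  if (config$write_per_scan)
    dir.create(scan_dir, recursive = TRUE, showWarnings = FALSE)

  # ---- gather inputs ----
  if (config$input == "synthetic") {
    sim <- config$sim
    sim$seed <- config$seed
    drawn <- generate_group_timeseries(sim)
    scans <- c(drawn$a, drawn$b)
    groups <- c(rep("A", length(drawn$a)), rep("B", length(drawn$b)))
    dmats <- NULL
  } else if (config$input == "files") {
    loaded <- read_timeseries_manifest(config$manifest)
    scans <- loaded$scans
    groups <- loaded$groups
    dmats <- NULL
  } else {
    loaded <- read_distance_manifest(config$manifest)
    dmats <- loaded$dmats
    scan_ids <- loaded$scan_ids
    groups <- loaded$groups
  }
  if (is.null(dmats)) {
    scan_ids <- vapply(scans, `[[`, character(1), "scan_id")
    dmats <- vector("list", length(scans))
  }

  # ---- per-scan topology ----
  barcodes <- vector("list", length(scan_ids))
  curves <- vector("list", length(scan_ids))
  for (i in seq_along(scan_ids)) {
    if (is.null(dmats[[i]])) {
      r <- pearson_fc(scans[[i]])
      d <- corr_to_distance(r)
      if (config$write_per_scan)
        write_labeled_matrix(r$values,
                             file.path(scan_dir, paste0(scan_ids[i], "_r.tsv")))
      dmats[[i]] <- d
    }
    if (config$write_per_scan)
      write_labeled_matrix(dmats[[i]]$values,
                           file.path(scan_dir, paste0(scan_ids[i], "_d.tsv")))
    stream <- build_simplex_stream(dmats[[i]], config$filtration)
    barcodes[[i]] <- reduce_boundary_matrix(stream)
    curves[[i]] <- betti_curve(barcodes[[i]])
    if (config$write_per_scan)
      write_barcode(barcodes[[i]],
                    file.path(scan_dir, paste0(scan_ids[i], "_barcode.tsv")))
  }

  # ---- group Betti curves + K-S ----
  grp_levels <- sort(unique(groups))
  grid <- curves[[1L]]$grid
  curve_tab <- data.frame(delta = grid)
  for (g in grp_levels) {
    cg <- curves[groups == g]
    curve_tab[[paste0("mean_beta0_", g)]] <-
      rowMeans(vapply(cg, `[[`, numeric(length(grid)), "beta0"))
    curve_tab[[paste0("mean_beta1_", g)]] <-
      rowMeans(vapply(cg, `[[`, numeric(length(grid)), "beta1"))
  }
  write.table(curve_tab, file.path(out, "betti_curves.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  two_groups <- length(grp_levels) == 2L &&
    all(table(groups) >= 2L)
  ks <- NULL
  if (two_groups) {
    ks <- betti_curve_group_test(curves[groups == grp_levels[1L]],
                                 curves[groups == grp_levels[2L]])
    ks_tab <- data.frame(
      dim = c(0L, 1L),
      D = c(ks$dim0$D, ks$dim1$D),
      Z = c(ks$dim0$Z, ks$dim1$Z),
      p = c(ks$dim0$p, ks$dim1$p))
    write.table(ks_tab, file.path(out, "ks_tests.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  # ---- FCNC features + comparison ----
  features <- per_scan_feature_table(
    barcodes, scan_ids, groups, thresholds = config$thresholds,
    lengths = config$medium_lengths, include_zero = config$include_zero)
  write.table(features, file.path(out, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(c(
    "features.tsv columns:",
    "  scan_id      scan identifier",
    "  group        group label",
    "  threshold    FCNC threshold delta (circuits with birth <= delta)",
    "  feature_type 'region' (per-region circuit involvement) or 'length'",
    "               (count of circuits with exactly that many edges)",
    "  feature      region label or circuit length",
    "  count        nonnegative integer feature value"),
    file.path(out, "features_schema.txt"))

  comparison <- NULL
  if (two_groups) {
    comparison <- compare_groups(features, alpha = config$alpha,
                                 fdr_scope = config$fdr_scope)
    write.table(comparison, file.path(out, "comparison.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    lq <- feature_quartiles(features[features$feature_type == "length", ])
    write.table(lq, file.path(out, "length_quartiles.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  labels <- barcodes[[1L]]$region_labels
  sig_regions <- character(0)
  sig_lengths <- character(0)
  if (!is.null(comparison)) {
    sig <- comparison[comparison$significant, ]
    sig_regions <- sort(unique(sig$feature[sig$feature_type == "region"]))
    sig_lengths <- sort(unique(sig$feature[sig$feature_type == "length"]))
  }
  summary <- list(
    package = "fcnc",
    version = as.character(utils::packageVersion("fcnc")),
    input = config$input,
    seed = config$seed,
    n_scans = as.list(table(groups)),
    n_regions = length(labels),
    regions = labels,
    thresholds = config$thresholds,
    medium_lengths = config$medium_lengths,
    alpha = config$alpha,
    stats_run = two_groups,
    n_significant_regions = length(sig_regions),
    significant_regions = sig_regions,
    significant_lengths = sig_lengths)
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(summary = summary, comparison = comparison, ks = ks,
                 features = features, curves = curves, barcodes = barcodes))
}
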