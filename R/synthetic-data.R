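# evaluate code under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed)
  force(code)
}

# canonical form of a ring: its undirected edge set, sorted
ring_edges <- function(ring) {
  ring <- as.integer(ring)
  nxt <- c(ring[-1L], ring[1L])
  e <- cbind(pmin(ring, nxt), pmax(ring, nxt))
  e[order(e[, 1L], e[, 2L]), , drop = FALSE]
}

validate_rings <- function(rings, n_regions, which) {
  for (ring in rings) {
    ring <- as.integer(ring)
    if (length(ring) < 3L)
      stop(which, ": a ring needs at least 3 regions")
    if (anyDuplicated(ring))
      stop(which, ": ring regions must be distinct")
    if (min(ring) < 1L || max(ring) > n_regions)
      stop(which, ": ring region index outside 1..", n_regions)
  }
  invisible(rings)
}

#' Simulation settings for two-group synthetic scans
#'
#' Describes a two-group resting-state experiment in which each scan is a
#' zero-mean multivariate normal time series whose population correlation
#' matrix embeds "planted cycles": rings of regions whose *adjacent* pairs
#' (ring neighbours only, not chords) correlate at `within_cycle_corr`
#' against a `background_corr` floor. Ring adjacency — rather than all pairs
#' within the ring — is what makes the planted structure a genuine
#' 1-dimensional hole: the ring's edges are short in \eqn{d = 1 - r} while
#' its chords stay long, so the loop cannot be filled by triangles until far
#' later in the filtration.
#'
#' Defaults mirror a typical clinical resting-state acquisition: 90 AAL
#' regions and 127 retained volumes (a 137-volume series minus 10 dummy
#' scans).
#'
#' The target correlation matrix of each group is validated at construction.
#' A ring with high adjacent correlation over a low background is typically
#' *not* positive semidefinite as written (the alternating-sign eigenvector
#' around the ring has negative eigenvalue); the nearest-PSD projection
#' (eigenvalue clipping at 1e-10, then renormalization to unit diagonal) is
#' applied automatically. The projection moderates the requested correlations
#' — e.g. ring adjacency 0.8 over background 0.1 becomes about 0.66 — but
#' preserves the planted topology: ring edges stay far shorter than chords in
#' \eqn{d = 1 - r}, so the 1-hole survives. An error naming the offending
#' parameters is raised only if the projection itself fails to produce a
#' positive-semidefinite matrix.
#'
#' @param n_scans_a,n_scans_b Number of scans per group (>= 1).
#' @param n_regions Number of regions (default 90).
#' @param n_timepoints Time points per scan (default 127, >= 3).
#' @param planted_cycles_a,planted_cycles_b Lists of integer vectors, each a
#'   ring of >= 3 distinct region indices.
#' @param within_cycle_corr,background_corr Correlations in `[0, 1)`.
#' @param noise_sd Marginal standard deviation of every region's signal (> 0).
#' @param seed Integer seed; identical configs give byte-identical data.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_scans_a, n_scans_b, n_regions = 90L,
                              n_timepoints = 127L,
                              planted_cycles_a = list(),
                              planted_cycles_b = list(),
                              within_cycle_corr = 0.8,
                              background_corr = 0.1,
                              noise_sd = 1, seed = 1L) {
  stopifnot(n_scans_a >= 1L, n_scans_b >= 1L, n_regions >= 3L,
            n_timepoints >= 3L, noise_sd > 0)
  if (within_cycle_corr < 0 || within_cycle_corr >= 1)
    stop("within_cycle_corr must lie in [0, 1)")
  if (background_corr < 0 || background_corr >= 1)
    stop("background_corr must lie in [0, 1)")
  validate_rings(planted_cycles_a, n_regions, "planted_cycles_a")
  validate_rings(planted_cycles_b, n_regions, "planted_cycles_b")
  config <- structure(
    list(n_scans_a = as.integer(n_scans_a), n_scans_b = as.integer(n_scans_b),
         n_regions = as.integer(n_regions),
         n_timepoints = as.integer(n_timepoints),
         planted_cycles_a = planted_cycles_a,
         planted_cycles_b = planted_cycles_b,
         within_cycle_corr = within_cycle_corr,
         background_corr = background_corr,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "simulation_config")
  target_covariance(config, "a")   # validates PSD feasibility
  target_covariance(config, "b")
  config
}

#' Population covariance of one simulated group
#'
#' Builds the target matrix (unit diagonal scaled by `noise_sd^2`,
#' `within_cycle_corr` on ring-adjacent pairs, `background_corr` elsewhere)
#' and projects it to the nearest positive-semidefinite correlation matrix by
#' eigenvalue clipping when needed. Useful in its own right: its
#' \eqn{1 - corr} distance matrix is the population-level ground truth that
#' sample scans converge to.
#'
#' @param config A [simulation_config()].
#' @param group `"a"` or `"b"`.
#' @return Covariance matrix `n_regions x n_regions`.
#' @export
target_covariance <- function(config, group = c("a", "b")) {
  group <- match.arg(group)
  rings <- if (group == "a") config$planted_cycles_a else config$planted_cycles_b
  p <- config$n_regions
  sigma <- matrix(config$background_corr, p, p)
  for (ring in rings) {
    e <- ring_edges(ring)
    sigma[e] <- config$within_cycle_corr
    sigma[e[, 2:1, drop = FALSE]] <- config$within_cycle_corr
  }
  diag(sigma) <- 1

  ev <- eigen(sigma, symmetric = TRUE)
  if (min(ev$values) < 1e-10) {
    vals <- pmax(ev$values, 1e-10)
    proj <- ev$vectors %*% (vals * t(ev$vectors))
    proj <- proj / tcrossprod(sqrt(diag(proj)))   # back to unit diagonal
    sigma <- (proj + t(proj)) / 2
    diag(sigma) <- 1
    resid <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
    if (resid < -1e-8)
      stop("covariance still not positive semidefinite after projection ",
           "(min eigenvalue ", signif(resid, 3), "): within_cycle_corr = ",
           config$within_cycle_corr, ", background_corr = ",
           config$background_corr)
  }
  sigma * config$noise_sd^2
}

#' Draw the two groups of synthetic scans
#'
#' Each scan is an independent draw of `n_timepoints` observations from
#' \eqn{N(0, \Sigma_g)} with the group's [target_covariance()]. The
#' generator's RNG is isolated: the caller's random state is untouched, and
#' identical configs reproduce identical scans.
#'
#' @param config A [simulation_config()].
#' @return List with elements `a` and `b`, each a list of [roi_timeseries()]
#'   (scan ids `A_01, A_02, ...` / `B_01, ...`).
#' @export
generate_group_timeseries <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  labels <- default_region_labels(config$n_regions)
  draw <- function(sigma, n_scans, prefix) {
    lapply(seq_len(n_scans), function(i) {
      x <- MASS::mvrnorm(config$n_timepoints, rep(0, config$n_regions), sigma)
      roi_timeseries(x, labels, sprintf("%s_%02d", prefix, i))
    })
  }
  with_seed(config$seed, {
    sa <- target_covariance(config, "a")
    sb <- target_covariance(config, "b")
    list(a = draw(sa, config$n_scans_a, "A"),
         b = draw(sb, config$n_scans_b, "B"))
  })
}

#' Regions expected to differ between the groups
#'
#' The planted ground truth: the union of regions belonging to rings present
#' (as undirected cycles) in exactly one group's configuration.
#'
#' @param config A [simulation_config()].
#' @return Sorted integer vector of region indices (possibly empty).
#' @export
planted_truth <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  key <- function(ring) paste(apply(ring_edges(ring), 1L, paste, collapse = "-"),
                              collapse = ";")
  ka <- vapply(config$planted_cycles_a, key, character(1))
  kb <- vapply(config$planted_cycles_b, key, character(1))
  only <- c(config$planted_cycles_a[!(ka %in% kb)],
            config$planted_cycles_b[!(kb %in% ka)])
  sort(unique(as.integer(unlist(only))))
}

#' Toy planar point clouds with known topology
#'
#' Small Euclidean fixtures for exercising the filtration and persistence
#' machinery: `"circle"` places `n` points evenly on the unit circle (one
#' 1-dimensional hole), `"two_blobs"` two Gaussian clusters (two components,
#' no hole), `"uniform_square"` uniform points on the unit square — except in
#' the degenerate case `n = 4, noise_sd = 0`, which returns the four unit
#' square corners exactly (the worked fixture: sides 1, diagonals
#' \eqn{\sqrt 2}).
#'
#' @param n Number of points (>= 1).
#' @param shape One of `"circle"`, `"two_blobs"`, `"uniform_square"`.
#' @param noise_sd Gaussian jitter SD.
#' @param seed Integer seed.
#' @return `n x 2` coordinate matrix (columns `x`, `y`).
#' @export
generate_point_cloud <- function(n, shape = c("circle", "two_blobs",
                                              "uniform_square"),
                                 noise_sd = 0, seed = 1L) {
  stopifnot(n >= 1L, noise_sd >= 0)
  shape <- match.arg(shape)
  with_seed(seed, {
    pts <- switch(shape,
      circle = {
        theta <- 2 * pi * (seq_len(n) - 1L) / n
        cbind(cos(theta), sin(theta)) + matrix(rnorm(2L * n, sd = noise_sd), n)
      },
      two_blobs = {
        centers <- rbind(c(0, 0), c(4, 0))[rep(1:2, length.out = n), ]
        centers + matrix(rnorm(2L * n, sd = max(noise_sd, 1e-3)), n)
      },
      uniform_square = {
        if (n == 4L && noise_sd == 0)
          rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
        else
          matrix(runif(2L * n), n) + matrix(rnorm(2L * n, sd = noise_sd), n)
      })
    colnames(pts) <- c("x", "y")
    rownames(pts) <- sprintf("P%d", seq_len(n))
    pts
  })
}

#' Euclidean distance matrix of a point cloud
#'
#' @param coords Coordinate matrix (rows = points).
#' @return A [distance_matrix()].
#' @export
point_cloud_distances <- function(coords) {
  labels <- rownames(coords)
  if (is.null(labels)) labels <- sprintf("P%d", seq_len(nrow(coords)))
  distance_matrix(as.matrix(dist(coords)), labels)
}

#' The unit-square worked fixture
#'
#' Four points at the unit square's corners: sides 1, diagonals \eqn{\sqrt 2}.
#' Its Vietoris-Rips barcode is known in closed form — one 1-dimensional
#' interval \eqn{[1, \sqrt 2)}, dim-0 deaths \eqn{\{1, 1, 1\}} plus one
#' infinite bar — making it the canonical end-to-end check.
#'
#' @return A 4-point [distance_matrix()].
#' @export
unit_square_distances <- function() {
  point_cloud_distances(generate_point_cloud(4L, "uniform_square", 0))
}

#' Write simulated scans and a manifest to disk
#'
#' One tab-delimited file per scan (header row of region labels, one row per
#' time point) plus `manifest.tsv` with columns `scan_id`, `group`, `path`
#' (relative to the manifest's directory) — the on-disk interchange format
#' read back by [read_timeseries_manifest()].
#'
#' @param scans A [generate_group_timeseries()] result (or any list of two
#'   groups of [roi_timeseries()], named by group).
#' @param dir Output directory (created if needed).
#' @return Path to the manifest file, invisibly.
#' @export
write_scans <- function(scans, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  groups <- names(scans)
  rows <- list()
  for (g in groups) {
    for (ts in scans[[g]]) {
      fname <- paste0(ts$scan_id, ".tsv")
      write.table(ts$values, file.path(dir, fname), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      rows[[length(rows) + 1L]] <-
        data.frame(scan_id = ts$scan_id, group = g, path = fname)
    }
  }
  manifest <- file.path(dir, "manifest.tsv")
  write.table(do.call(rbind, rows), manifest, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(manifest)
}
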