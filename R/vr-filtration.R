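#' Vietoris-Rips filtration settings
#'
#' Defaults mirror the standard analysis configuration for correlation-derived
#' brain networks: simplices up to dimension 2 (so 0- and 1-dimensional
#' homology can be computed), maximum filtration value \eqn{t_{max} = 0.9}
#' (i.e. correlation at least 0.1), and a 450-division grid used when Betti
#' curves are sampled. The grid is a reporting device only: the simplex stream
#' and barcode always use exact pairwise distances as filtration values.
#'
#' @param d_max Maximum simplex dimension, 1 or 2.
#' @param t_max Maximum filtration value (> 0).
#' @param divisions Number of grid divisions for Betti-curve sampling (>= 1).
#' @return An object of class `filtration_config`.
#' @export
filtration_config <- function(d_max = 2L, t_max = 0.9, divisions = 450L) {
  d_max <- as.integer(d_max)
  if (!d_max %in% c(1L, 2L)) stop("d_max must be 1 or 2")
  if (!is.numeric(t_max) || length(t_max) != 1L || t_max <= 0)
    stop("t_max must be a positive number")
  divisions <- as.integer(divisions)
  if (divisions < 1L) stop("divisions must be >= 1")
  structure(list(d_max = d_max, t_max = t_max, divisions = divisions),
            class = "filtration_config")
}

betti_grid <- function(config) {
  seq(0, config$t_max, length.out = config$divisions + 1L)
}

#' Build the filtered Vietoris-Rips simplex stream
#'
#' Enumerates, in filtration order, every simplex of the Vietoris-Rips complex
#' up to `config$d_max` and `config$t_max`: all vertices at value 0; an edge
#' \eqn{[ab]} at value \eqn{d(a,b)} whenever \eqn{d(a,b) \le t_{max}}; a
#' triangle whenever all three of its edges are present, at the maximum of
#' their values (the triangle value is taken as `max()` of stored edge values,
#' never recomputed, so the equality is exact). Ties are broken by dimension
#' then lexicographic vertex order, which fixes the reduction and hence the
#' representative cycles.
#'
#' Triangles are found by scanning edges and intersecting the neighbour sets
#' of their endpoints, which is far cheaper than cubic enumeration on the
#' dense 90-region graphs this package targets.
#'
#' @param d A [distance_matrix()].
#' @param config A [filtration_config()].
#' @return An object of class `simplex_stream`: parallel vectors `dim` and
#'   `value`, an `m x 3` vertex-index matrix `verts` (NA-padded, 1-based),
#'   `n_vertices`, `region_labels` and the `config`.
#' @export
#' @examples
#' d <- distance_matrix(matrix(c(0, .5, .5, 0), 2), c("a", "b"))
#' build_simplex_stream(d, filtration_config(t_max = 0.9))
build_simplex_stream <- function(d, config = filtration_config()) {
  stopifnot(inherits(d, "distance_matrix"), inherits(config, "filtration_config"))
  dm <- d$values
  n <- nrow(dm)
  adj <- dm <= config$t_max
  diag(adj) <- FALSE

  ut <- which(adj & upper.tri(dm), arr.ind = TRUE)
  ei <- ut[, 1L]; ej <- ut[, 2L]
  ev <- dm[ut]

  dims <- c(rep.int(0L, n), rep.int(1L, length(ei)))
  v1 <- c(seq_len(n), ei)
  v2 <- c(rep(NA_integer_, n), ej)
  v3 <- rep(NA_integer_, n + length(ei))
  vals <- c(rep.int(0, n), ev)

  if (config$d_max >= 2L && length(ei)) {
    ti <- vector("list", length(ei)); tj <- ti; tk <- ti; tv <- ti
    for (e in seq_along(ei)) {
      i <- ei[e]; j <- ej[e]
      k <- which(adj[i, ] & adj[j, ])
      k <- k[k > j]
      if (length(k)) {
        ti[[e]] <- rep.int(i, length(k)); tj[[e]] <- rep.int(j, length(k))
        tk[[e]] <- k
        tv[[e]] <- pmax(ev[e], dm[cbind(i, k)], dm[cbind(j, k)])
      }
    }
    ti <- unlist(ti); tj <- unlist(tj); tk <- unlist(tk); tv <- unlist(tv)
    if (length(ti)) {
      dims <- c(dims, rep.int(2L, length(ti)))
      v1 <- c(v1, ti); v2 <- c(v2, tj); v3 <- c(v3, tk)
      vals <- c(vals, tv)
    }
  }

  ord <- order(vals, dims, v1, v2, v3, na.last = FALSE, method = "radix")
  structure(
    list(dim = dims[ord],
         verts = cbind(v0 = v1[ord], v1 = v2[ord], v2 = v3[ord]),
         value = vals[ord],
         n_vertices = n,
         region_labels = d$region_labels,
         config = config),
    class = "simplex_stream")
}

#' @export
print.simplex_stream <- function(x, ...) {
  cat("<simplex_stream> ", x$n_vertices, " vertices, ",
      sum(x$dim == 1L), " edges, ", sum(x$dim == 2L),
      " triangles up to t_max = ", x$config$t_max, "\n", sep = "")
  invisible(x)
}

#' Count simplices of one dimension up to a threshold
#'
#' @param stream A [build_simplex_stream()] result.
#' @param delta Threshold in `[0, t_max]`.
#' @param dim Simplex dimension (0, 1 or 2, and at most the stream's `d_max`).
#' @return Integer count of simplices of that dimension with filtration value
#'   `<= delta`.
#' @export
simplex_count <- function(stream, delta, dim) {
  stopifnot(inherits(stream, "simplex_stream"))
  if (delta < 0 || delta > stream$config$t_max)
    stop("delta must lie in [0, t_max]")
  dim <- as.integer(dim)
  if (dim > stream$config$d_max)
    stop("dim ", dim, " exceeds the stream's d_max = ", stream$config$d_max)
  sum(stream$dim == dim & stream$value <= delta)
}

#' Export a simplex stream as delimited text
#'
#' One row per simplex with columns `dim, v0, v1, v2, filtration_value`
#' (vertex columns blank where absent), in filtration order.
#'
#' @param stream A [build_simplex_stream()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_simplex_stream <- function(stream, path) {
  df <- data.frame(dim = stream$dim,
                   v0 = stream$verts[, 1L],
                   v1 = stream$verts[, 2L],
                   v2 = stream$verts[, 3L],
                   filtration_value = stream$value)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
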