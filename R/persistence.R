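#' Persistence barcode by boundary-matrix reduction
#'
#' Computes the 0- and 1-dimensional persistence pairing of a filtered
#' Vietoris-Rips stream by the standard column reduction of the boundary
#' matrix over GF(2), processing simplices in filtration order. Every vertex
#' opens a connected component at value 0 (so there are exactly `n_vertices`
#' dim-0 intervals — the elder rule: when an edge merges two components the
#' younger one dies). An edge whose reduced boundary vanishes closes a loop
#' and opens a dim-1 class; the reduction's accumulated column at that moment
#' is stored as the class's representative cycle (every vertex touches an even
#' number of its edges, and every edge is born no later than the class). A
#' triangle may later fill the youngest unpaired loop. Classes still open at
#' `t_max` are right-censored with death `Inf`.
#'
#' Representatives are the reduced-column cycles at birth, not shortest
#' cycles; per-region circuit counts downstream inherit this convention.
#'
#' @param stream A [build_simplex_stream()] result (filtration order and face
#'   closure are required and checked).
#' @return An object of class `barcode`: `intervals` (data frame with columns
#'   `dim`, `birth`, `death`, `creator` — the component-creating vertex for
#'   dim 0, `NA` for dim 1), `representatives` (list parallel to the rows;
#'   `k x 2` matrices of 1-based vertex indices for dim-1 rows), plus
#'   `n_vertices`, `region_labels`, `config`.
#' @export
#' @examples
#' d <- unit_square_distances()
#' bc <- reduce_boundary_matrix(build_simplex_stream(d, filtration_config(t_max = 2)))
#' subset(bc$intervals, dim == 1)   # one loop: born 1, filled at sqrt(2)
reduce_boundary_matrix <- function(stream) {
  stopifnot(inherits(stream, "simplex_stream"))
  if (is.unsorted(stream$value))
    stop("stream violates filtration order: values must be non-decreasing")
  verts0 <- stream$verts - 1L
  verts0[is.na(verts0)] <- -1L
  res <- ph_reduce_cpp(stream$dim, verts0, stream$value, stream$n_vertices)

  n0 <- length(res$vertex)
  n1 <- length(res$birth1)
  intervals <- data.frame(
    dim = c(rep.int(0L, n0), rep.int(1L, n1)),
    birth = c(rep.int(0, n0), res$birth1),
    death = c(res$death0, res$death1),
    creator = c(res$vertex + 1L, rep(NA_integer_, n1)))
  reps <- c(vector("list", n0), lapply(res$reps, function(m) m + 1L))
  structure(
    list(intervals = intervals, representatives = reps,
         n_vertices = stream$n_vertices,
         region_labels = stream$region_labels, config = stream$config),
    class = "barcode")
}

#' @export
print.barcode <- function(x, ...) {
  iv <- x$intervals
  pos1 <- sum(iv$dim == 1L & iv$death > iv$birth)
  cat("<barcode> ", x$n_vertices, " dim-0 intervals; ", sum(iv$dim == 1L),
      " dim-1 intervals (", pos1, " with positive persistence)\n", sep = "")
  invisible(x)
}

#' Betti curves on the filtration grid
#'
#' Samples \eqn{\beta_0} (number of connected branches) and \eqn{\beta_1}
#' (number of independent loops) at `divisions + 1` evenly spaced thresholds
#' on \eqn{[0, t_{max}]}. An interval is counted at grid point \eqn{\delta}
#' when \eqn{birth \le \delta < death} (half-open, so zero-length bars never
#' contribute).
#'
#' @param barcode A [reduce_boundary_matrix()] result.
#' @param config A [filtration_config()]; defaults to the one the barcode was
#'   built with.
#' @return An object of class `betti_curve`: `grid`, `beta0`, `beta1`.
#' @export
betti_curve <- function(barcode, config = barcode$config) {
  stopifnot(inherits(barcode, "barcode"))
  grid <- betti_grid(config)
  iv <- barcode$intervals
  count_open <- function(birth, death) {
    # open intervals at g: #(birth <= g) - #(death <= g); zero-length cancel
    findInterval(grid, sort(birth)) -
      findInterval(grid, sort(death[is.finite(death)]))
  }
  structure(
    list(grid = grid,
         beta0 = count_open(iv$birth[iv$dim == 0L], iv$death[iv$dim == 0L]),
         beta1 = count_open(iv$birth[iv$dim == 1L], iv$death[iv$dim == 1L])),
    class = "betti_curve")
}

#' Connected components of the thresholded distance graph
#'
#' Independent oracle for \eqn{\beta_0}: builds the graph whose edges are the
#' region pairs with \eqn{d_{ij} \le \delta} and counts its connected
#' components (via igraph, an implementation with no code in common with the
#' boundary-matrix reduction).
#'
#' @param d A [distance_matrix()].
#' @param delta Threshold, `>= 0`.
#' @return Integer component count.
#' @export
connected_components_at <- function(d, delta) {
  stopifnot(inherits(d, "distance_matrix"), delta >= 0)
  adj <- d$values <= delta
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(g)$no
}

# GF(2) matrix rank by Gaussian elimination; M coerced to 0/1
rank_gf2 <- function(M) {
  if (is.null(dim(M)) || any(dim(M) == 0L)) return(0L)
  M <- matrix(as.logical(M %% 2L), nrow(M), ncol(M))
  r <- 0L
  for (col in seq_len(ncol(M))) {
    piv <- which(M[, col])
    piv <- piv[piv > r]
    if (!length(piv)) next
    r <- r + 1L
    if (piv[1L] != r) M[c(r, piv[1L]), ] <- M[c(piv[1L], r), ]
    hit <- which(M[, col])
    hit <- hit[hit != r]
    if (length(hit)) M[hit, ] <- xor(M[hit, , drop = FALSE],
                                     rep(M[r, ], each = length(hit)))
    if (r == nrow(M)) break
  }
  r
}

#' Brute-force homology ranks at one threshold
#'
#' Validation oracle: restricts the stream to simplices with filtration value
#' `<= delta`, assembles the full dim-1 and dim-2 boundary matrices over
#' GF(2), and returns \eqn{\beta_0 = V - rank(\partial_1)} and
#' \eqn{\beta_1 = (E - rank(\partial_1)) - rank(\partial_2)} by Gaussian
#' elimination. Exponentially simpler than the persistence reduction (no
#' filtration order, no pairing), so the two routes are genuinely
#' independent; intended for small instances.
#'
#' @param stream A [build_simplex_stream()] result.
#' @param delta Threshold in `[0, t_max]`.
#' @return Named integer vector `c(beta0 = , beta1 = )`.
#' @export
homology_ranks_bruteforce <- function(stream, delta) {
  stopifnot(inherits(stream, "simplex_stream"))
  keep <- stream$value <= delta
  dims <- stream$dim[keep]
  verts <- stream$verts[keep, , drop = FALSE]
  nv <- sum(dims == 0L)
  if (nv == 0L) stop("sub-stream at delta is empty")
  ed <- verts[dims == 1L, 1:2, drop = FALSE]
  tr <- verts[dims == 2L, , drop = FALSE]
  ne <- nrow(ed); nt <- nrow(tr)

  b1 <- matrix(0L, nv, ne)
  if (ne) {
    b1[cbind(ed[, 1L], seq_len(ne))] <- 1L
    b1[cbind(ed[, 2L], seq_len(ne))] <- 1L
  }
  edge_id <- function(i, j) match(paste(i, j), paste(ed[, 1L], ed[, 2L]))
  b2 <- matrix(0L, max(ne, 1L), nt)
  if (nt) {
    b2[cbind(edge_id(tr[, 1L], tr[, 2L]), seq_len(nt))] <- 1L
    b2[cbind(edge_id(tr[, 1L], tr[, 3L]), seq_len(nt))] <- 1L
    b2[cbind(edge_id(tr[, 2L], tr[, 3L]), seq_len(nt))] <- 1L
  }
  r1 <- if (ne) rank_gf2(b1) else 0L
  r2 <- if (nt) rank_gf2(b2) else 0L
  c(beta0 = nv - r1, beta1 = (ne - r1) - r2)
}

format_representative <- function(rep) {
  if (is.null(rep) || !nrow(rep)) return("")
  paste(sprintf("%d-%d", rep[, 1L], rep[, 2L]), collapse = ";")
}

#' Export a barcode (or persistence diagram) as delimited text
#'
#' Columns `dim`, `birth`, `death` (literal `inf` for right-censored bars)
#' and, unless `diagram = TRUE`, the dim-1 representative cycles as
#' semicolon-joined `i-j` edge tokens of 1-based region indices.
#'
#' @param barcode A [reduce_boundary_matrix()] result.
#' @param path Output file path.
#' @param diagram If `TRUE`, omit the representative column.
#' @return `path`, invisibly.
#' @export
write_barcode <- function(barcode, path, diagram = FALSE) {
  iv <- barcode$intervals
  df <- data.frame(dim = iv$dim, birth = iv$birth,
                   death = ifelse(is.finite(iv$death),
                                  format(iv$death, digits = 17), "inf"))
  if (!diagram)
    df$representative <- vapply(barcode$representatives,
                                format_representative, character(1))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
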