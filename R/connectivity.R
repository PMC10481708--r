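#' ROI time-series container
#'
#' Holds one scan's region-averaged signals: a numeric matrix with one row per
#' time point and one column per brain region. This is the starting point of
#' the pipeline; everything upstream (volume registration, band-pass
#' filtering, atlas-based extraction) is assumed done.
#'
#' @param values Numeric matrix, `n_timepoints x n_regions`, no missing values,
#'   at least 3 time points.
#' @param region_labels Character vector of unique region names; defaults to
#'   the AAL-90 names when there are 90 columns, else `V1..Vn`.
#' @param scan_id Scan identifier string.
#' @return An object of class `roi_timeseries` with a `zero_variance` attribute
#'   flagging constant regions (they are tolerated here but rejected by
#'   [pearson_fc()]).
#' @seealso [pearson_fc()]
#' @export
roi_timeseries <- function(values, region_labels = NULL, scan_id = "scan") {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("time-series values must be numeric")
  if (anyNA(values)) stop("time-series values contain missing entries")
  if (nrow(values) < 3L) stop("need at least 3 time points, got ", nrow(values))
  n_regions <- ncol(values)
  if (is.null(region_labels)) region_labels <- colnames(values)
  if (is.null(region_labels)) region_labels <- default_region_labels(n_regions)
  region_labels <- as.character(region_labels)
  if (length(region_labels) != n_regions)
    stop("got ", length(region_labels), " labels for ", n_regions, " regions")
  if (anyDuplicated(region_labels))
    stop("duplicated region labels: ",
         paste(unique(region_labels[duplicated(region_labels)]), collapse = ", "))
  colnames(values) <- region_labels
  zv <- apply(values, 2L, sd) == 0
  structure(
    list(values = values, region_labels = region_labels,
         scan_id = as.character(scan_id)),
    zero_variance = region_labels[zv],
    class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat("<roi_timeseries> scan '", x$scan_id, "': ", nrow(x$values),
      " time points x ", length(x$region_labels), " regions\n", sep = "")
  invisible(x)
}

new_labeled_square <- function(m, labels, class) {
  dimnames(m) <- list(labels, labels)
  structure(list(values = m, region_labels = labels), class = class)
}

#' Functional-connectivity (correlation) matrix
#'
#' Constructor with validation: symmetric, unit diagonal, entries in
#' \eqn{[-1, 1]}.
#'
#' @param r Square numeric matrix of correlations.
#' @param region_labels Region names (defaults taken from `dimnames`).
#' @return An object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(r, region_labels = NULL) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop("correlation matrix must be square")
  if (is.null(region_labels)) region_labels <- rownames(r)
  if (is.null(region_labels)) region_labels <- default_region_labels(nrow(r))
  if (max(abs(r - t(r))) > 1e-12) stop("correlation matrix is not symmetric")
  if (any(abs(diag(r) - 1) > 0)) stop("correlation diagonal must be exactly 1")
  if (min(r) < -1 - 1e-12 || max(r) > 1 + 1e-12)
    stop("correlations outside [-1, 1]")
  r <- (r + t(r)) / 2
  diag(r) <- 1
  new_labeled_square(r, as.character(region_labels), "connectivity_matrix")
}

#' Distance matrix over regions
#'
#' Constructor with validation: symmetric, zero diagonal, nonnegative. The
#' correlation-derived distance \eqn{d = 1 - r} lies in \eqn{[0, 2]}; generic
#' metric inputs (e.g. Euclidean point clouds used as fixtures) may exceed 2
#' and are accepted. Note \eqn{1 - r} need not satisfy the triangle
#' inequality; nothing downstream assumes it does.
#'
#' @param d Square numeric matrix of nonnegative distances.
#' @param region_labels Region names (defaults taken from `dimnames`).
#' @return An object of class `distance_matrix`.
#' @export
distance_matrix <- function(d, region_labels = NULL) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (is.null(region_labels)) region_labels <- rownames(d)
  if (is.null(region_labels)) region_labels <- default_region_labels(nrow(d))
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix is not symmetric")
  if (any(diag(d) != 0)) stop("distance diagonal must be exactly 0")
  if (min(d) < 0) stop("negative distances")
  d <- (d + t(d)) / 2
  diag(d) <- 0
  new_labeled_square(d, as.character(region_labels), "distance_matrix")
}

#' Pearson functional connectivity of one scan
#'
#' Computes the sample Pearson correlation between every pair of
#' region-averaged time courses,
#' \deqn{m_{ij} = \mathrm{corr}(P_i, P_j),}
#' the standard static functional-connectivity estimate. Constant (zero
#' variance) regions make the correlation undefined and are an error: in this
#' pipeline they signal a degenerate simulation or extraction, not data to be
#' patched over.
#'
#' @param ts A [roi_timeseries()].
#' @return A [connectivity_matrix()].
#' @export
#' @examples
#' ts <- roi_timeseries(matrix(rnorm(60), 20, 3), c("A", "B", "C"), "demo")
#' pearson_fc(ts)$values
pearson_fc <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  zv <- attr(ts, "zero_variance")
  if (length(zv))
    stop("zero-variance region(s): ", paste(zv, collapse = ", "))
  r <- cor(ts$values)
  diag(r) <- 1
  connectivity_matrix(r, ts$region_labels)
}

#' Correlation-to-distance transform
#'
#' Maps functional connectivity to a dissimilarity, \eqn{d_{ij} = 1 - r_{ij}}:
#' perfectly correlated regions are at distance 0, uncorrelated at 1,
#' anti-correlated at 2. With the default maximum filtration value 0.9 this
#' means only region pairs with \eqn{r \ge 0.1} ever form an edge of the
#' Vietoris-Rips complex; negative correlations are never connected.
#'
#' @param c A [connectivity_matrix()].
#' @return A [distance_matrix()] with entries in \eqn{[0, 2]}.
#' @export
corr_to_distance <- function(c) {
  stopifnot(inherits(c, "connectivity_matrix"))
  d <- 1 - c$values
  diag(d) <- 0
  distance_matrix(pmin(pmax(d, 0), 2), c$region_labels)
}
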