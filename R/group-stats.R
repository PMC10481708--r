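#' Two-sample Mann-Whitney U test
#'
#' Two-sided rank-sum test via [stats::wilcox.test()]. Exact enumeration is
#' used for small samples (`n_x + n_y <= 12`) without ties; otherwise the
#' normal approximation with tie and continuity corrections. The returned `U`
#' is the x-side Mann-Whitney statistic (`wilcox.test`'s `W`).
#'
#' @param x,y Nonempty numeric samples.
#' @param exact Force exact (`TRUE`) or approximate (`FALSE`) computation;
#'   default `NULL` applies the rule above.
#' @return List with `U`, `p`, and the `exact` flag used.
#' @export
mann_whitney_u <- function(x, y, exact = NULL) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  pooled <- c(x, y)
  ties <- anyDuplicated(pooled) > 0L
  if (is.null(exact)) exact <- (length(pooled) <= 12L) && !ties
  if (length(unique(pooled)) == 1L)   # fully tied: no evidence either way
    return(list(U = length(x) * length(y) / 2, p = 1, exact = FALSE))
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE,
                alternative = "two.sided"))
  list(U = unname(wt$statistic), p = min(wt$p.value, 1), exact = exact && !ties)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: with p-values sorted ascending,
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, returned in input order
#' (delegates to [stats::p.adjust()]).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
#' @examples
#' bh_fdr(c(0.003, 0.006, 0.005))   # 0.006 0.006 0.006
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE) || anyNA(p_values))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Two-sample Kolmogorov-Smirnov test with asymptotic Z
#'
#' Computes \eqn{D = \sup_t |F_x(t) - F_y(t)|}, the scaled statistic
#' \eqn{Z = D \sqrt{n_x n_y / (n_x + n_y)}}, and the two-sided p-value from
#' the asymptotic Kolmogorov distribution (via [stats::ks.test()] with
#' `exact = FALSE`; ties, ubiquitous in pooled Betti-number samples, make the
#' p-value approximate).
#'
#' @param x,y Nonempty numeric samples.
#' @return List with `D`, `Z`, `p`, `n_x`, `n_y`.
#' @export
ks_two_sample <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  kt <- suppressWarnings(ks.test(x, y, exact = FALSE))
  D <- unname(kt$statistic)
  n_x <- length(x); n_y <- length(y)
  list(D = D, Z = D * sqrt(n_x * n_y / (n_x + n_y)),
       p = kt$p.value, n_x = n_x, n_y = n_y)
}

#' Two-group comparison of FCNC features
#'
#' For every feature (region or circuit length) at every threshold, compares
#' the two groups' per-scan counts by the two-sided Mann-Whitney U test, then
#' adjusts p-values by Benjamini-Hochberg. The default FDR family is the
#' feature's own thresholds (m = number of thresholds, typically 3) — each
#' region is corrected across its three thresholds, separately from other
#' regions; `fdr_scope = "global"` instead pools every test into one family.
#'
#' @param features Long feature table from [per_scan_feature_table()].
#' @param alpha Significance level for the `significant` flag.
#' @param fdr_scope `"within_feature"` (default) or `"global"`.
#' @return Data frame with one row per feature x threshold: group means and
#'   SDs, `U`, `p_value`, `q_value`, `significant`. Group order is
#'   alphabetical; the group names are recorded in attributes `group_a` and
#'   `group_b`.
#' @export
compare_groups <- function(features, alpha = 0.05,
                           fdr_scope = c("within_feature", "global")) {
  fdr_scope <- match.arg(fdr_scope)
  grp <- sort(unique(features$group))
  if (length(grp) != 2L)
    stop("need exactly two groups, got: ", paste(grp, collapse = ", "))
  for (g in grp)
    if (length(unique(features$scan_id[features$group == g])) < 2L)
      stop("group '", g, "' has fewer than 2 scans")

  cell <- interaction(features$feature_type, features$feature,
                      features$threshold, drop = TRUE)
  idx <- split(seq_len(nrow(features)), cell)
  rows <- lapply(idx, function(i) {
    f <- features[i, ]
    x <- f$count[f$group == grp[1L]]
    y <- f$count[f$group == grp[2L]]
    mw <- mann_whitney_u(x, y)
    data.frame(feature_type = f$feature_type[1L], feature = f$feature[1L],
               threshold = f$threshold[1L],
               mean_a = mean(x), sd_a = sd(x), n_a = length(x),
               mean_b = mean(y), sd_b = sd(y), n_b = length(y),
               U = mw$U, p_value = mw$p)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$feature_type, out$feature, out$threshold), ]
  rownames(out) <- NULL

  if (fdr_scope == "within_feature") {
    fam <- interaction(out$feature_type, out$feature, drop = TRUE)
    out$q_value <- NA_real_
    for (i in split(seq_len(nrow(out)), fam))
      out$q_value[i] <- bh_fdr(out$p_value[i])
  } else {
    out$q_value <- bh_fdr(out$p_value)
  }
  out$significant <- out$q_value < alpha
  attr(out, "group_a") <- grp[1L]
  attr(out, "group_b") <- grp[2L]
  out
}

#' Group comparison of Betti curves
#'
#' Pools each scan's Betti numbers over every grid point into one sample per
#' group and dimension, then applies the two-sample Kolmogorov-Smirnov test —
#' a distributional comparison of the curves at all scales at once.
#'
#' @param curves_a,curves_b Lists of [betti_curve()] objects (all on the same
#'   grid).
#' @return List with elements `dim0` and `dim1`, each a [ks_two_sample()]
#'   result.
#' @export
betti_curve_group_test <- function(curves_a, curves_b) {
  grids <- lapply(c(curves_a, curves_b), `[[`, "grid")
  for (g in grids[-1L])
    if (!isTRUE(all.equal(g, grids[[1L]], tolerance = 0)))
      stop("Betti curves are not on a common grid")
  pool <- function(curves, what) unlist(lapply(curves, `[[`, what))
  list(dim0 = ks_two_sample(pool(curves_a, "beta0"), pool(curves_b, "beta0")),
       dim1 = ks_two_sample(pool(curves_a, "beta1"), pool(curves_b, "beta1")))
}

#' Per-group quartile summary of features
#'
#' Tabulates min, quartiles and max of the per-scan counts for each feature,
#' threshold and group — the numeric content of a box plot, as a table.
#'
#' @param features Long feature table from [per_scan_feature_table()].
#' @return Data frame with columns `feature_type`, `feature`, `threshold`,
#'   `group`, `min`, `q1`, `median`, `q3`, `max`.
#' @export
feature_quartiles <- function(features) {
  cell <- interaction(features$feature_type, features$feature,
                      features$threshold, features$group, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(features)), cell), function(i) {
    f <- features[i, ]
    q <- quantile(f$count, c(0, .25, .5, .75, 1), names = FALSE)
    data.frame(feature_type = f$feature_type[1L], feature = f$feature[1L],
               threshold = f$threshold[1L], group = f$group[1L],
               min = q[1L], q1 = q[2L], median = q[3L], q3 = q[4L], max = q[5L])
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$feature_type, out$feature, out$threshold, out$group), ]
  rownames(out) <- NULL
  out
}
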