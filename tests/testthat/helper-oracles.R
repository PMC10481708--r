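# Independent brute-force oracles and fixture builders used across tests.

# step-up BH from first principles (no p.adjust)
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- (m / seq_len(m)) * p[ord]
  for (i in (m - 1):1) if (m > 1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# exact two-sided Mann-Whitney p by enumerating every group labeling
mwu_enum_oracle <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  u_of <- function(idx) {
    xs <- pooled[idx]
    ys <- pooled[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(seq_len(nx))
  us <- combn(length(pooled), nx, u_of)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  list(U = u_obs, p = min(p, 1))
}

# KS D by sweeping the pooled sorted values
ks_d_oracle <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

# beta_k at an arbitrary threshold straight from barcode intervals
beta_at <- function(barcode, delta, dim) {
  iv <- barcode$intervals
  sum(iv$dim == dim & iv$birth <= delta & delta < iv$death)
}

# random symmetric matrix with distinct positive off-diagonal entries;
# metric = TRUE draws Euclidean points instead (triangle inequality holds)
random_distance <- function(n, seed, metric = FALSE) {
  set.seed(seed)
  if (metric) {
    point_cloud_distances(matrix(runif(3L * n), n))
  } else {
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- runif(n * (n - 1L) / 2, 0.05, 1)
    distance_matrix(m + t(m))
  }
}

# a small synthetic two-group feature table built through the real pipeline
make_group_features <- function(n_a = 4L, n_b = 4L, n_regions = 16L,
                                n_timepoints = 80L, ring = list(1:5),
                                seed = 101L, thresholds = c(0.7, 0.8, 0.9)) {
  cfg <- simulation_config(n_a, n_b, n_regions = n_regions,
                           n_timepoints = n_timepoints,
                           planted_cycles_a = ring, seed = seed)
  g <- generate_group_timeseries(cfg)
  scans <- c(g$a, g$b)
  groups <- c(rep("A", n_a), rep("B", n_b))
  bcs <- lapply(scans, function(ts)
    reduce_boundary_matrix(build_simplex_stream(corr_to_distance(pearson_fc(ts)))))
  ids <- vapply(scans, `[[`, character(1), "scan_id")
  per_scan_feature_table(bcs, ids, groups, thresholds = thresholds)
}
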