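test_that("identical configs give byte-identical scans and leave the caller's RNG alone", {
  cfg <- simulation_config(2, 2, n_regions = 10, n_timepoints = 30,
                           planted_cycles_a = list(1:4), seed = 5L)
  set.seed(999)
  before <- .Random.seed
  g1 <- generate_group_timeseries(cfg)
  expect_identical(.Random.seed, before)
  g2 <- generate_group_timeseries(cfg)
  expect_identical(lapply(g1$a, `[[`, "values"), lapply(g2$a, `[[`, "values"))
  expect_identical(lapply(g1$b, `[[`, "values"), lapply(g2$b, `[[`, "values"))
  expect_equal(g1$a[[1]]$scan_id, "A_01")
})

test_that("zero-correlation configs produce asymptotically independent series", {
  cfg <- simulation_config(1, 1, n_regions = 10, n_timepoints = 5000,
                           within_cycle_corr = 0, background_corr = 0, seed = 2L)
  r <- pearson_fc(generate_group_timeseries(cfg)$a[[1]])$values
  off <- r[upper.tri(r)]
  expect_lt(mean(abs(off)), 0.2)
  expect_lt(max(abs(off)), 0.2)
})

test_that("sample correlations converge to the (projected) population target", {
  cfg <- simulation_config(1, 1, n_regions = 12, n_timepoints = 10000,
                           planted_cycles_a = list(1:4),
                           within_cycle_corr = 0.5, background_corr = 0.2,
                           seed = 3L)
  target <- cov2cor(target_covariance(cfg, "a"))
  r <- pearson_fc(generate_group_timeseries(cfg)$a[[1]])$values
  expect_lt(max(abs(r - target)), 0.05)
})

test_that("a planted 6-ring is a genuine 1-hole of the population metric", {
  cfg <- simulation_config(1, 1, n_regions = 6, n_timepoints = 500,
                           planted_cycles_a = list(1:6),
                           within_cycle_corr = 0.9, background_corr = 0.05,
                           seed = 4L)
  pop <- cov2cor(target_covariance(cfg, "a"))
  d <- distance_matrix(1 - pop)
  dv <- d$values
  ring <- cbind(1:6, c(2:6, 1))
  ringmask <- matrix(FALSE, 6, 6)
  ringmask[ring] <- TRUE
  ringmask <- ringmask | t(ringmask)
  # ring edges sit well below delta = 0.5, all chords well above
  expect_true(all(dv[ring] < 0.5))
  expect_true(all(dv[upper.tri(dv) & !ringmask] > 0.5))
  st <- build_simplex_stream(d, filtration_config(t_max = 0.6))
  expect_equal(unname(homology_ranks_bruteforce(st, 0.5)["beta1"]), 1)
})

test_that("infeasible ring parameters are projected rather than fatal, and validated", {
  expect_error(simulation_config(1, 1, within_cycle_corr = 1.2), "within_cycle_corr")
  expect_error(simulation_config(1, 1, background_corr = -0.1), "background_corr")
  expect_error(
    simulation_config(1, 1, n_regions = 8, planted_cycles_a = list(1:2)),
    "at least 3")
  expect_error(
    simulation_config(1, 1, n_regions = 8, planted_cycles_a = list(c(1, 1, 2))),
    "distinct")
  expect_error(
    simulation_config(1, 1, n_regions = 8, planted_cycles_a = list(7:10)),
    "outside")
  # heavily conflicting request succeeds via projection and stays PSD
  cfg <- simulation_config(1, 1, n_regions = 10, planted_cycles_a = list(1:6),
                           within_cycle_corr = 0.9, background_corr = 0.05)
  ev <- eigen(target_covariance(cfg, "a"), symmetric = TRUE, only.values = TRUE)
  expect_gte(min(ev$values), -1e-8)
})

test_that("point clouds have the advertised geometry", {
  pc <- generate_point_cloud(10, "circle", noise_sd = 0)
  d <- point_cloud_distances(pc)$values
  expect_true(all(diag(d) == 0))
  expect_identical(d, t(d))
  expect_equal(max(d), 2, tolerance = 1e-12)  # unit-circle diameter

  sq <- generate_point_cloud(4, "uniform_square", noise_sd = 0)
  ds <- point_cloud_distances(sq)$values
  expect_equal(sort(unique(round(ds[upper.tri(ds)], 12))), c(1, sqrt(2)))

  expect_error(generate_point_cloud(10, "pentagon"), "arg")
})

test_that("a noiseless 10-point circle has exactly one persistent loop", {
  d <- point_cloud_distances(generate_point_cloud(10, "circle", noise_sd = 0))
  st <- build_simplex_stream(d, filtration_config(t_max = 2.01))
  bc <- reduce_boundary_matrix(st)
  iv <- bc$intervals
  pos1 <- iv[iv$dim == 1 & iv$death > iv$birth, ]
  expect_equal(nrow(pos1), 1)
  expect_equal(pos1$birth, 2 * sin(pi / 10), tolerance = 1e-12)
  # independent route agrees mid-filtration
  expect_equal(unname(homology_ranks_bruteforce(st, 0.8)), c(1, 1))
})

test_that("planted truth is the symmetric difference of the groups' rings", {
  mk <- function(a, b) simulation_config(1, 1, n_regions = 10,
                                         planted_cycles_a = a,
                                         planted_cycles_b = b)
  expect_identical(planted_truth(mk(list(1:4), list(1:4))), integer(0))
  expect_identical(planted_truth(mk(list(1:4), list())), 1:4)
  expect_identical(planted_truth(mk(list(1:3), list(1:3, 4:6))), 4:6)
  # same ring written from a different starting vertex is the same cycle
  expect_identical(planted_truth(mk(list(c(1, 2, 3, 4)), list(c(3, 4, 1, 2)))),
                   integer(0))
})

test_that("scan files and manifest round-trip through disk", {
  cfg <- simulation_config(2, 1, n_regions = 6, n_timepoints = 20, seed = 8L)
  g <- generate_group_timeseries(cfg)
  dir <- withr::local_tempdir()
  manifest <- write_scans(g, dir)
  expect_true(file.exists(manifest))
  loaded <- read_timeseries_manifest(manifest)
  expect_equal(length(loaded$scans), 3)
  expect_equal(loaded$groups, c("a", "a", "b"))
  expect_equal(loaded$scans[[1]]$values, g$a[[1]]$values, tolerance = 1e-12)
})
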