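test_that("Mann-Whitney U handles the canonical boundary cases", {
  # identical samples: dead-center statistic, no evidence
  r <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$U, 4.5)
  expect_equal(r$p, 1)
  # complete separation of 3 vs 3: exact two-sided p = 2/20
  r <- mann_whitney_u(1:3, 10:12)
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)
  expect_true(r$exact)
  # constant pooled sample
  r <- mann_whitney_u(rep(2, 5), rep(2, 7))
  expect_equal(r$p, 1)
  expect_error(mann_whitney_u(numeric(0), 1:3), "nonempty")
})

test_that("exact mode equals full enumeration over all labelings", {
  set.seed(101)
  for (i in 1:20) {
    x <- round(rnorm(sample(3:6, 1)), 2)
    y <- round(rnorm(sample(3:6, 1)) + 0.5, 2)
    if (anyDuplicated(c(x, y))) next
    got <- mann_whitney_u(x, y, exact = TRUE)
    want <- mwu_enum_oracle(x, y)
    expect_equal(got$U, want$U)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
})

test_that("the normal approximation tracks the exact p on small samples", {
  set.seed(102)
  devs <- replicate(100, {
    x <- rnorm(10); y <- rnorm(10)
    abs(mann_whitney_u(x, y, exact = TRUE)$p -
          mann_whitney_u(x, y, exact = FALSE)$p)
  })
  expect_lt(max(devs), 0.01)
})

test_that("BH q-values equal the step-up oracle exactly on random vectors", {
  set.seed(103)
  for (i in 1:1000) {
    p <- runif(sample(1:12, 1))
    expect_identical(bh_fdr(p), bh_oracle(p))
  }
  expect_equal(bh_fdr(0.2), 0.2)
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("within-family BH reproduces published FCNC q-value triples", {
  # p-value triples over thresholds 0.7/0.8/0.9 and their FDR-corrected
  # q-values as printed for the nine regions and two medium-length rows
  cases <- list(
    Precentral_L      = list(p = c(0.046, 0.039, 0.052), q = c(0.0520, 0.0520, 0.0520)),
    Frontal_Inf_Orb_R = list(p = c(0.192, 0.014, 0.013), q = c(0.1920, 0.0210, 0.0210)),
    Olfactory_R       = list(p = c(0.672, 0.059, 0.043), q = c(0.6720, 0.0885, 0.0885)),
    Cuneus_R          = list(p = c(0.008, 0.018, 0.021), q = c(0.0210, 0.0210, 0.0210)),
    Lingual_R         = list(p = c(0.035, 0.010, 0.008), q = c(0.0350, 0.0150, 0.0150)),
    Occipital_Inf_R   = list(p = c(0.041, 0.293, 0.293), q = c(0.1230, 0.2930, 0.2930)),
    Fusiform_R        = list(p = c(0.003, 0.006, 0.005), q = c(0.006, 0.006, 0.006)),
    Pallidum_R        = list(p = c(0.085, 0.007, 0.010), q = c(0.0850, 0.0150, 0.0150)),
    Heschl_R          = list(p = c(0.013, 0.027, 0.027), q = c(0.027, 0.027, 0.027)),
    medium_len_8      = list(p = c(0.091, 0.017, 0.029), q = c(0.091, 0.043, 0.043)),
    medium_len_9      = list(p = c(0.004, 0.008, 0.007), q = c(0.008, 0.008, 0.008)))
  for (nm in names(cases)) {
    got <- bh_fdr(cases[[nm]]$p)
    expect_true(max(abs(got - cases[[nm]]$q)) <= 5.1e-4,
                label = paste0(nm, ": q = ", paste(got, collapse = ", ")))
  }
})

test_that("KS statistic matches the ECDF sweep and the Z identity", {
  expect_equal(ks_two_sample(1:8, 1:8)$D, 0)
  r <- ks_two_sample(1:5, 6:10)
  expect_equal(r$D, 1)
  set.seed(104)
  for (i in 1:25) {
    x <- sample(0:5, 12, replace = TRUE)   # heavy ties on purpose
    y <- sample(0:5, 9, replace = TRUE) + rbinom(9, 1, 0.4)
    r <- ks_two_sample(x, y)
    expect_equal(r$D, ks_d_oracle(x, y), tolerance = 1e-12)
    expect_equal(r$Z / max(r$D, 1e-300),
                 sqrt(length(x) * length(y) / (length(x) + length(y))),
                 tolerance = 1e-12)
  }
  # D = 0.5 at 8 vs 8 gives Z = 1 exactly
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  expect_equal(ks_two_sample(x, x + 4.5)$Z,
               ks_two_sample(x, x + 4.5)$D * 2)
})

test_that("Betti-curve group test pools grid values and demands a shared grid", {
  d <- unit_square_distances()
  cfgf <- filtration_config(t_max = 2, divisions = 50)
  cv <- betti_curve(reduce_boundary_matrix(build_simplex_stream(d, cfgf)))
  same <- betti_curve_group_test(list(cv, cv), list(cv, cv))
  expect_equal(same$dim0$D, 0)
  expect_equal(same$dim1$D, 0)

  shifted <- cv
  shifted$beta1 <- cv$beta1 + 1
  diffres <- betti_curve_group_test(list(cv), list(shifted))
  # mass on {0,1} against {1,2}: ECDF gap is the zero-fraction of the curve
  expect_equal(diffres$dim1$D, mean(cv$beta1 == 0), tolerance = 1e-12)

  other <- betti_curve(reduce_boundary_matrix(
    build_simplex_stream(d, filtration_config(t_max = 2, divisions = 60))))
  expect_error(betti_curve_group_test(list(cv), list(other)), "grid")
})

test_that("compare_groups is null on duplicated groups and errors on degenerate input", {
  ft <- make_group_features(n_a = 3, n_b = 3, seed = 105)
  # identical groups: copy group A's counts onto B scan-by-scan
  ids_a <- unique(ft$scan_id[ft$group == "A"])
  ids_b <- unique(ft$scan_id[ft$group == "B"])
  for (i in seq_along(ids_b)) {
    src <- ft$count[ft$scan_id == ids_a[i]]
    ft$count[ft$scan_id == ids_b[i]] <- src
  }
  cmp <- compare_groups(ft)
  expect_true(all(cmp$p_value == 1))
  expect_false(any(cmp$significant))
  expect_true(all(cmp$q_value >= cmp$p_value - 1e-12))

  one <- ft[ft$scan_id %in% c(ids_a, ids_b[1]), ]
  expect_error(compare_groups(one), "fewer than 2 scans")
  three <- ft
  three$group[three$scan_id == ids_b[1]] <- "C"
  expect_error(compare_groups(three), "exactly two groups")
})

test_that("global FDR scope corrects across the full feature family", {
  ft <- make_group_features(n_a = 4, n_b = 4, seed = 106)
  within <- compare_groups(ft, fdr_scope = "within_feature")
  global <- compare_groups(ft, fdr_scope = "global")
  expect_equal(within$p_value, global$p_value)
  expect_true(all(global$q_value >= within$q_value - 1e-12))
})

test_that("feature quartiles summarize each group's counts", {
  ft <- make_group_features(n_a = 3, n_b = 3, seed = 107, thresholds = 0.8)
  fq <- feature_quartiles(ft[ft$feature_type == "length", ])
  expect_equal(nrow(fq), 2)   # one length feature x two groups
  expect_true(all(fq$min <= fq$median & fq$median <= fq$max))
})
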