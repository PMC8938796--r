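test_that("default sensitivity model has full rank and an iodine K-edge step", {
  A <- make_sensitivity_model(c(25, 34, 50, 60), c("I", "PE", "CS"))
  expect_equal(dim(A$entries), c(4L, 3L))
  expect_equal(qr(A$entries)$rank, 3L)
  # K-edge at 33.2 keV: iodine response steps up from the 25 to the 34 keV
  # bin, then decreases with energy
  iod <- A$entries[, "I"]
  expect_gt(iod[2], iod[1])
  expect_gt(iod[2], iod[3])
  expect_gt(iod[3], iod[4])
  # photoelectric falls steeply, Compton nearly flat
  expect_true(all(diff(A$entries[, "PE"]) < 0))

  A3 <- make_sensitivity_model(c(30, 45, 60), c("I", "PE", "CS"))
  expect_equal(qr(A3$entries)$rank, 3L)
  expect_error(make_sensitivity_model(c(30, 60), c("I", "PE", "CS")),
               "rank deficiency")
})

test_that("noiseless forward model is exactly A times the material vector", {
  sim <- make_uniform_subject(grid = c(24, 24, 24), iodine = 5)
  A <- make_sensitivity_model()
  v <- c(13, 11, 12) # a tumor voxel
  expect_true(sim$truth$tumor_mask[v[1], v[2], v[3]])
  x <- c(sim$truth$iodine[v[1], v[2], v[3]], sim$truth$pe[v[1], v[2], v[3]],
         sim$truth$cs[v[1], v[2], v[3]])
  b <- vapply(sim$spectral$bins, function(bn) bn[v[1], v[2], v[3]], 0)
  expect_equal(unname(b), as.numeric(A$entries %*% x), tolerance = 1e-12)
  expect_equal(x[1], 5) # uniform tumor iodine
  expect_equal(unname(sim$eid[v[1], v[2], v[3]]),
               sum(eid_sensitivity_row() * x), tolerance = 1e-12)
})

test_that("same spec and seed give bit-identical volumes", {
  spec <- phantom_spec(grid_shape = c(16, 16, 16), noise_sd = 0.02, seed = 42)
  s1 <- simulate_subject(spec)
  s2 <- simulate_subject(spec)
  expect_identical(s1$spectral$bins, s2$spectral$bins)
  expect_identical(s1$eid, s2$eid)
  expect_identical(s1$truth$iodine, s2$truth$iodine)
})

test_that("per-bin noise has the configured standard deviation", {
  grid <- c(48, 48, 48)
  sigma <- 0.05
  spec0 <- phantom_spec(grid_shape = grid, noise_sd = 0, seed = 7)
  spec1 <- phantom_spec(grid_shape = grid, noise_sd = sigma, seed = 7)
  s0 <- simulate_subject(spec0)
  s1 <- simulate_subject(spec1)
  for (b in 1:4) {
    emp <- sd(s1$spectral$bins[[b]] - s0$spectral$bins[[b]])
    expect_lt(abs(emp - sigma) / sigma, 0.05)
  }
})

test_that("vial simulation supports exact sensitivity re-estimation", {
  A <- make_sensitivity_model()
  vi <- simulate_calibration_vials(A, rbind(c(10, 0, 0), c(0, 1, 0), c(0, 0, 1)), 0)
  # basis vials: measurement rows are the matrix columns scaled by the
  # concentrations
  expect_equal(unname(vi$intensities[1, ]), unname(10 * A$entries[, 1]))
  expect_equal(unname(vi$intensities[2, ]), unname(A$entries[, 2]))
  A_hat <- estimate_sensitivity(vi)
  expect_equal(unname(A_hat$entries), unname(A$entries), tolerance = 1e-10)

  # small noise: estimate within a few sd of the truth
  set.seed(5)
  vi_n <- simulate_calibration_vials(
    A, rbind(c(10, 0, 0), c(5, 0, 0), c(0, 1, 0), c(0, 0.5, 0),
             c(0, 0, 1), c(2, 1, 1)), noise_sd = 1e-4)
  A_n <- estimate_sensitivity(vi_n)
  expect_lt(max(abs(A_n$entries - A$entries)), 50 * 1e-4)

  expect_warning(simulate_calibration_vials(A, rbind(c(1, 0, 0), c(2, 0, 0), c(3, 0, 0)), 0),
                 "degenerate")
})

test_that("cohort has the requested composition and deterministic seeds", {
  eff <- cohort_effect(noise_sd = 0)
  co <- simulate_cohort(13, 12, eff, seed = 3, grid_shape = c(12, 12, 12))
  expect_length(co$subjects, 25L)
  expect_equal(unname(co$class_counts), c(13L, 12L))
  labs <- vapply(co$subjects, `[[`, "", "class_label")
  expect_equal(sum(labs == "positive"), 13L)
  co2 <- simulate_cohort(13, 12, eff, seed = 3, grid_shape = c(12, 12, 12))
  expect_identical(co$subjects[[5]]$truth$iodine, co2$subjects[[5]]$truth$iodine)
})

test_that("class iodine shift is recovered across cohorts", {
  eff <- cohort_effect(shift = 2, sigma_between = 1, texture_amplitude = 0,
                       noise_sd = 0)
  diffs <- vapply(1:25, function(s) {
    co <- simulate_cohort(4, 4, eff, seed = s, grid_shape = c(12, 12, 12))
    mns <- vapply(co$subjects, function(su) mean(su$truth$iodine[su$truth$tumor_mask]), 0)
    labs <- vapply(co$subjects, `[[`, "", "class_label")
    mean(mns[labs == "positive"]) - mean(mns[labs == "negative"])
  }, 0)
  # mean shift 2, se = sigma_between * sqrt(1/4 + 1/4) / sqrt(25) = 0.14
  # (clipping at zero can bias the means slightly; allow 5 se)
  expect_lt(abs(mean(diffs) - 2), 0.7)
})

test_that("decomposition inverts the noiseless forward model", {
  sim <- make_uniform_subject(grid = c(20, 20, 20), iodine = 4)
  A <- make_sensitivity_model()
  maps <- decompose(sim$spectral, A)
  expect_lt(max(abs(maps$iodine - sim$truth$iodine)), 1e-8)
  expect_lt(max(abs(maps$pe - sim$truth$pe)), 1e-8)
  expect_lt(max(abs(maps$cs - sim$truth$cs)), 1e-8)
})

test_that("null cohorts produce no excess univariate discoveries", {
  # no class effect at all: same mean, texture and noise for both classes
  null_eff <- cohort_effect(shift = 0, sigma_between = 1,
                            corr_length_pos = 2, corr_length_neg = 2,
                            texture_amplitude = 0.8)
  n_rep <- 50
  any_hit <- vapply(seq_len(n_rep), function(r) {
    co <- simulate_cohort(3, 3, null_eff, seed = 4000 + r,
                          grid_shape = c(16, 16, 16))
    feats <- t(vapply(co$subjects, function(s) {
      firstorder_features(s$eid, s$truth$tumor_mask, s$spec$voxel_size_mm,
                          bin_width = 0.004)
    }, numeric(18)))
    labs <- vapply(co$subjects, `[[`, "", "class_label")
    any(univariate_screen(as.data.frame(feats), labs)$significant)
  }, TRUE)
  # family-wise false-positive rate at most ~alpha; binomial 99.5% bound
  expect_lte(sum(any_hit), qbinom(0.995, n_rep, 0.05))
})
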