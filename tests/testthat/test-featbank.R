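test_that("fixed-bin-width discretization follows the floor rule", {
  d <- c(4, 1, 1)
  v <- array(c(0, 24.9, 25, 100), d)
  m <- array(TRUE, d)
  dz <- discretize(v, m, 25)
  expect_equal(as.vector(dz$levels), c(1L, 1L, 2L, 5L))
  expect_equal(dz$n_levels, 5L)
  # constant region: a single level
  dzc <- discretize(array(7, d), m, 25)
  expect_equal(unique(as.vector(dzc$levels)), 1L)
  # doubling the width never increases the level count
  set.seed(71)
  v2 <- array(runif(64, 0, 300), c(4, 4, 4))
  m2 <- array(TRUE, c(4, 4, 4))
  for (bw in c(10, 20, 40)) {
    expect_gte(discretize(v2, m2, bw)$n_levels,
               discretize(v2, m2, 2 * bw)$n_levels)
  }
  expect_error(discretize(v, m, 0), "positive")
})

test_that("first-order features match direct statistics", {
  d <- c(10, 10, 1)
  v <- array(as.numeric(1:100), d)
  m <- array(TRUE, d)
  f <- firstorder_features(v, m, voxel_size_mm = 2, bin_width = 10)
  expect_equal(unname(f["Mean"]), mean(1:100))
  expect_equal(unname(f["Variance"]), mean((1:100 - 50.5)^2))
  expect_equal(unname(f["Median"]), median(1:100))
  expect_equal(unname(f["10Percentile"]), unname(quantile(1:100, 0.1)))
  expect_equal(unname(f["90Percentile"]), unname(quantile(1:100, 0.9)))
  expect_equal(unname(f["InterquartileRange"]),
               unname(diff(quantile(1:100, c(0.25, 0.75)))))
  expect_equal(unname(f["Energy"]), sum((1:100)^2))
  expect_equal(unname(f["TotalEnergy"]), 8 * sum((1:100)^2))
  expect_equal(unname(f["RootMeanSquared"]), sqrt(mean((1:100)^2)))
  # symmetric sample: zero skewness
  expect_lt(abs(f["Skewness"]), 1e-12)

  # constant region limits
  fc <- firstorder_features(array(4, d), m, 1, 25)
  expect_equal(unname(fc["Mean"]), 4)
  expect_equal(unname(fc["Variance"]), 0)
  expect_equal(unname(fc["Entropy"]), 0)
  expect_equal(unname(fc["Uniformity"]), 1)
  expect_equal(unname(fc["Skewness"]), 0)
})

test_that("mesh shape features approach analytic values", {
  ball <- make_ball(c(48, 48, 48), 20)
  s <- shape_features(ball, voxel_size_mm = 1)
  expect_length(s, 14L)
  expect_gte(unname(s["Sphericity"]), 0.97)
  expect_lte(unname(s["Sphericity"]), 1.0)
  expect_equal(unname(s["VoxelVolume"]), sum(ball))

  # cube of side 16: mesh volume within 1% of the analytic volume
  cube <- array(FALSE, c(24, 24, 24)); cube[5:20, 5:20, 5:20] <- TRUE
  sc <- shape_features(cube, voxel_size_mm = 1)
  expect_lt(abs(sc["MeshVolume"] - 16^3) / 16^3, 0.01)

  # a 1 x 1 x 10 rod is far less "round" than a cube
  rod <- array(FALSE, c(12, 12, 16)); rod[6, 6, 4:13] <- TRUE
  sr <- shape_features(rod, voxel_size_mm = 1)
  expect_lt(unname(sr["Elongation"]), unname(sc["Elongation"]))
  expect_gt(unname(sr["MajorAxisLength"]), unname(sr["LeastAxisLength"]))

  # degenerate single voxel is defined and flagged
  one <- array(FALSE, c(7, 7, 7)); one[4, 4, 4] <- TRUE
  so <- shape_features(one, 1)
  expect_true(all(is.finite(so)))
  expect_true(attr(so, "degenerate"))
})

test_that("extract_all yields exactly 851 uniquely named features", {
  set.seed(72)
  d <- c(16, 16, 16)
  v <- array(rnorm(prod(d), 100, 25), d)
  m <- make_ball(d, 5)
  fv <- extract_all(v, m, "EID", voxel_size_mm = 0.125, bin_width = 25)
  expect_length(fv, 851L)
  expect_equal(anyDuplicated(names(fv)), 0L)
  expect_true(all(is.finite(fv)))
  # census: 14 shape + 93 on the original + 93 x 8 wavelet = 107 + 744
  nm <- names(fv)
  expect_equal(sum(grepl("^original_shape_", nm)), 14L)
  expect_equal(sum(grepl("^original_", nm)), 107L)
  expect_equal(sum(grepl("^wavelet-", nm)), 744L)
  fams <- pcdradiomics:::texture_census()
  for (fam in names(fams)) {
    expect_equal(sum(grepl(paste0("^original_", fam, "_"), nm)), fams[[fam]])
  }
  expect_equal(sum(grepl("^original_firstorder_", nm)), 18L)
  # naming convention: transform_family_feature_source
  expect_true("original_shape_Sphericity_EID" %in% nm)
  expect_true(all(grepl("_EID$", nm)))
})

test_that("features are invariant under even-shift translation", {
  set.seed(73)
  d <- c(20, 20, 20)
  v <- array(0, d)
  patch <- array(rnorm(6^3, 50, 20), c(6, 6, 6))
  m <- array(FALSE, d)
  v[4:9, 4:9, 4:9] <- patch; m[4:9, 4:9, 4:9] <- TRUE
  v2 <- array(0, d); m2 <- array(FALSE, d)
  v2[6:11, 8:13, 10:15] <- patch; m2[6:11, 8:13, 10:15] <- TRUE
  f1 <- extract_all(v, m, "EID", 1, 10)
  f2 <- extract_all(v2, m2, "EID", 1, 10)
  expect_equal(unname(f1), unname(f2), tolerance = 1e-8)
})

test_that("cohort extraction produces the three grouped tables", {
  eff <- cohort_effect(noise_sd = 0.01)
  co <- simulate_cohort(2, 2, eff, seed = 8, grid_shape = c(24, 24, 24))
  tabs <- extract_cohort(co)
  expect_named(tabs, c("EID", "PCD", "MaterialMaps"))
  expect_equal(dim(tabs$EID), c(4L, 851L))
  expect_equal(dim(tabs$PCD), c(4L, 3404L))
  expect_equal(dim(tabs$MaterialMaps), c(4L, 2553L))
  for (tb in tabs) {
    expect_equal(anyDuplicated(colnames(tb)), 0L)
    expect_false(anyNA(tb))
  }
  expect_equal(attr(tabs$PCD, "class_labels"),
               c("positive", "positive", "negative", "negative"))
  # shape features depend on the mask only: identical across the 4 bins
  shp <- grep("^original_shape_MeshVolume_PCD", colnames(tabs$PCD), value = TRUE)
  expect_length(shp, 4L)
  expect_equal(unname(as.numeric(tabs$PCD[1, shp])),
               rep(tabs$PCD[1, shp[1]], 4L), ignore_attr = TRUE)
})
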