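test_that("recovery coefficient and COV basics", {
  grid <- voxel_grid(10, 10, 3, 2, 2, 2)
  vals <- array(50, c(10, 10, 3))
  img <- volume_image(vals, grid, "reconstructed")
  roi <- array(FALSE, c(10, 10, 3)); roi[3:6, 3:6, 2] <- TRUE
  expect_equal(recovery_coefficient(img, roi, 50), 1)
  z <- volume_image(array(0, c(10, 10, 3)), grid, "reconstructed")
  expect_equal(recovery_coefficient(z, roi, 50), 0)
  expect_error(recovery_coefficient(img, roi & FALSE, 50), "empty")
  # COV: two-voxel ROI {1, 3} -> population SD 1, mean 2 -> 0.5
  v2 <- array(0, c(10, 10, 3)); v2[1, 1, 1] <- 1; v2[2, 1, 1] <- 3
  img2 <- volume_image(v2, grid, "reconstructed")
  roi2 <- array(FALSE, c(10, 10, 3)); roi2[1:2, 1, 1] <- TRUE
  expect_equal(roi_cov(img2, roi2), 0.5)
  # scale invariance and constant case
  img3 <- volume_image(v2 * 7, grid, "reconstructed")
  expect_equal(roi_cov(img3, roi2), 0.5)
  expect_equal(roi_cov(img, roi), 0)
  expect_error(roi_cov(z, roi), "zero")
})

test_that("voxelwise mean/STD maps", {
  grid <- voxel_grid(4, 4, 2, 1, 1, 1)
  a <- volume_image(array(0, c(4, 4, 2)), grid, "reconstructed")
  b <- volume_image(array(2, c(4, 4, 2)), grid, "reconstructed")
  ms <- voxelwise_mean_std(list(a, b))
  expect_true(all(ms$mean$values == 1))
  expect_true(all(ms$std$values == 1))
  ms2 <- voxelwise_mean_std(list(b, a))      # order invariance
  expect_identical(ms2$mean$values, ms$mean$values)
  expect_identical(ms2$std$values, ms$std$values)
  same <- voxelwise_mean_std(list(b, b, b))
  expect_true(all(same$std$values == 0))
  expect_error(voxelwise_mean_std(list(a)), "2")
})

test_that("Freedman-Diaconis histograms", {
  # 1..8: type-7 IQR = 3.5, width = 2 * 3.5 * 8^(-1/3) = 3.5
  h <- fd_histogram(1:8)
  expect_equal(diff(h$breaks)[1], 3.5)
  expect_equal(sum(h$counts), 8)
  # constant data falls back to a single bin
  hc <- fd_histogram(rep(4, 10))
  expect_length(hc$counts, 1)
  expect_equal(sum(hc$counts), 10)
  set.seed(3)
  x <- stats::rnorm(500)
  hx <- fd_histogram(x)
  expect_equal(sum(hx$counts), 500)
  expect_error(fd_histogram(1), "2")
})

test_that("intensity features: skewness, peak and constant-ROI identities", {
  grid <- voxel_grid(4, 1, 1, 10, 10, 10)
  img <- volume_image(array(c(1, 1, 1, 10), c(4, 1, 1)), grid,
                      "reconstructed")
  roi <- array(TRUE, c(4, 1, 1))
  f <- suppressWarnings(intensity_features(img, roi))
  expect_equal(f$skewness, 1.1547, tolerance = 1e-4)
  expect_equal(f$mean, 3.25)
  expect_equal(f$median, 1)
  # constant ROI: skewness 0 and peak = mean
  imgc <- volume_image(array(5, c(4, 1, 1)), grid, "reconstructed")
  fc <- suppressWarnings(intensity_features(imgc, roi))
  expect_equal(fc$skewness, 0)
  expect_equal(fc$peak, 5)
  # peak of a single hot voxel averages down over the 1 cm^3 sphere
  grid2 <- voxel_grid(15, 15, 15, 4, 4, 4)
  v <- array(0, c(15, 15, 15)); v[8, 8, 8] <- 100
  img2 <- volume_image(v, grid2, "reconstructed")
  f2 <- intensity_features(img2, array(TRUE, c(15, 15, 15)))
  expect_lt(f2$peak, 100)
  expect_gt(f2$peak, 0)
})

test_that("GLCM features: constant ROI, hand-enumerated checkerboard, and
           independence", {
  grid <- voxel_grid(6, 6, 1, 1, 1, 1)
  const <- volume_image(array(500, c(6, 6, 1)), grid, "reconstructed")
  roi <- array(TRUE, c(6, 6, 1))
  f <- glcm_features(const, roi, bin_width = 100)
  expect_equal(f$energy, 1)
  expect_equal(f$joint_entropy, 0)
  expect_equal(f$homogeneity, 1)
  # 2x2 checkerboard of levels {1, 2} at 0 degrees: all pairs (1,2)/(2,1)
  grid2 <- voxel_grid(2, 2, 1, 1, 1, 1)
  cb <- volume_image(array(c(50, 150, 150, 50), c(2, 2, 1)), grid2,
                     "reconstructed")
  counts <- petsim:::glcm_counts_direction(
    array(floor(cb$values / 100) + 1L, c(2, 2, 1)),
    array(TRUE, c(2, 2, 1)), c(1L, 0L))
  pmat <- counts / sum(counts)
  f0 <- petsim:::glcm_features_one(pmat)
  expect_equal(f0$energy, 0.5)
  expect_equal(f0$joint_entropy, 1)
  # independent random levels -> correlation near 0
  set.seed(7)
  grid3 <- voxel_grid(60, 60, 1, 1, 1, 1)
  rnd <- volume_image(array(sample(0:7, 3600, TRUE) * 100 + 1,
                            c(60, 60, 1)), grid3, "reconstructed")
  fr <- glcm_features(rnd, array(TRUE, c(60, 60, 1)), bin_width = 100)
  expect_lt(abs(fr$correlation), 0.05)
  # direction-order invariance comes from averaging: energy in (0, 1]
  expect_true(fr$energy > 0 && fr$energy <= 1)
  expect_error(glcm_features(const, roi & FALSE), "empty")
})

test_that("feature regression recovers exact linear relations", {
  x <- c(1, 2, 3, 4, 5, 7)
  r1 <- compare_features(x, x)
  expect_equal(r1$slope, 1, tolerance = 1e-12)
  expect_equal(r1$intercept, 0, tolerance = 1e-12)
  expect_equal(r1$pearson_r, 1)
  r2 <- compare_features(x, 2 * x + 1)
  expect_equal(r2$slope, 2, tolerance = 1e-12)
  expect_equal(r2$intercept, 1, tolerance = 1e-10)
  # r^2 equals regression R^2 for simple regression
  set.seed(1)
  y <- 3 * x + stats::rnorm(6)
  r3 <- compare_features(x, y)
  fit <- stats::lm(y ~ x)
  R2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  expect_equal(r3$pearson_r^2, R2, tolerance = 1e-12)
  expect_error(compare_features(rep(1, 5), 1:5), "variance")
})

test_that("NEMA ROIs match the inserted spheres and avoid them in the
           background", {
  grid <- voxel_grid(200, 160, 60, 1.65, 1.65, 3)
  nema <- make_nema_iq(grid, supersample = 1)
  rois <- nema_rois(grid, nema$spec)
  vox_ml <- 1.65 * 1.65 * 3 / 1000
  for (k in seq_len(6)) {
    d <- nema$spec$sphere_diameters_mm[k]
    analytic <- 4 / 3 * pi * (d / 2)^3 / 1000
    layer <- 4 * pi * (d / 2)^2 * 3 / 1000   # one voxel layer allowance
    expect_lt(abs(sum(rois$spheres[[k]]) * vox_ml - analytic), layer)
  }
  for (k in seq_len(6))
    expect_false(any(rois$background & rois$spheres[[k]]))
  zidx <- unique(which(rois$background, arr.ind = TRUE)[, 3])
  expect_length(zidx, 5)
  # background sits in warm background on the ground-truth map
  expect_equal(mean(nema$activity$values[rois$background]), 2930,
               tolerance = 1e-6)
})
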