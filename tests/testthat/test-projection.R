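test_that("forward projection preserves counts and handles zero input", {
  g <- tiny_geometry(); grid <- tiny_grid()
  img <- random_volume(grid, seed = 1)
  s <- forward_project(img, g)
  expect_lt(abs(sum(s$values) - sum(img$values)) / sum(img$values), 1e-6)
  # TOF-summed projection preserves counts too, and reproduces non-TOF
  st <- forward_project(img, g, tof = TRUE)
  expect_lt(abs(sum(st$values) - sum(img$values)) / sum(img$values), 1e-6)
  expect_lt(max(abs(apply(st$values, 1:3, sum) - s$values)) /
              max(s$values), 1e-6)
  z <- volume_image(array(0, c(32, 32, 4)), grid, "activity")
  expect_identical(sum(forward_project(z, g)$values), 0)
  neg <- img; neg$values[1] <- -1
  expect_error(forward_project(neg, g), "non-negative")
  wide <- random_volume(voxel_grid(300, 300, 4, 2, 2, 4))
  expect_error(forward_project(wide, g), "bore")
})

test_that("line integrals reproduce analytic chord lengths of a disk", {
  # unit-attenuation disk: -10 log(attenuation factor) is the chord in mm
  g <- scanner_geometry("chord", ring_radius_mm = 200, n_projections = 100,
                        n_views = 8, n_planes = 1, span = 1, n_tof_bins = 1,
                        tof_bin_width_ps = 100, timing_resolution_ps = 200,
                        fov_transaxial_mm = 200, fov_axial_mm = 2)
  grid <- voxel_grid(200, 200, 1, 1, 1, 2)
  R <- 80
  disk <- rasterize(phantom_spec(list(
    shape("cylinder", c(0, 0, 0), c(R, 10), attenuation = 1))),
    grid, 3, "attenuation")
  af <- attenuation_factors(disk, g)
  soff <- (seq_len(100) - 50.5) * 2
  for (v in c(1, 3, 6)) {
    chord_meas <- -10 * log(af$values[, v, 1])
    inside <- abs(soff) < 0.9 * R
    chord_true <- 2 * sqrt(pmax(R^2 - soff^2, 0))
    expect_lt(max(abs(chord_meas[inside] - chord_true[inside]) /
                    chord_true[inside]), 0.01)
  }
})

test_that("back projection is the exact adjoint of forward projection", {
  g <- tiny_geometry(); grid <- tiny_grid()
  for (sd in 1:3) {
    x <- random_volume(grid, seed = sd)
    set.seed(100 + sd)
    y <- array(stats::runif(48 * 24 * 4), c(48, 24, 4))
    Ax <- forward_project(x, g)
    Aty <- back_project(sinogram(y, g), g, grid)
    lhs <- sum(Ax$values * y); rhs <- sum(x$values * Aty$values)
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
  }
  # TOF pair is adjoint as well
  x <- random_volume(grid, seed = 9)
  set.seed(42)
  yt <- array(stats::runif(48 * 24 * 4 * 5), c(48, 24, 4, 5))
  lhs <- sum(forward_project(x, g, tof = TRUE)$values * yt)
  rhs <- sum(x$values *
               back_project(sinogram(yt, g, tof = TRUE), g, grid)$values)
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
  # structural cases
  zs <- zero_sinogram(g)
  expect_identical(sum(back_project(zs, g, grid)$values), 0)
  ones <- sinogram(array(1, c(48, 24, 4)), g)
  bp <- back_project(ones, g, grid)
  expect_true(all(bp$values[16:17, 16:17, ] > 0))
})

test_that("attenuation factors follow the exponential survival law", {
  g <- tiny_geometry(); grid <- tiny_grid()
  mu0 <- volume_image(array(0, c(32, 32, 4)), grid, "attenuation")
  expect_true(all(attenuation_factors(mu0, g)$values == 1))
  # 20 cm of water on the central LOR -> exp(-1.92) within 1%
  gw <- scanner_geometry("water", ring_radius_mm = 300, n_projections = 120,
                         n_views = 4, n_planes = 1, span = 1, n_tof_bins = 1,
                         tof_bin_width_ps = 100, timing_resolution_ps = 200,
                         fov_transaxial_mm = 240, fov_axial_mm = 2)
  gridw <- voxel_grid(120, 120, 1, 2, 2, 2)
  water <- rasterize(phantom_spec(list(
    shape("cylinder", c(0, 0, 0), c(100, 10), attenuation = 0.096))),
    gridw, 3, "attenuation")
  af <- attenuation_factors(water, gw)
  central <- af$values[which.min(abs((seq_len(120) - 60.5) * 2)), 1, 1]
  expect_lt(abs(central - exp(-1.92)) / exp(-1.92), 0.01)
  # doubling mu squares every factor
  water2 <- volume_image(water$values * 2, gridw, "attenuation")
  af2 <- attenuation_factors(water2, gw)
  expect_equal(af2$values, af$values^2, tolerance = 1e-4)
  # bounded in (0, 1], monotone decreasing in mu
  expect_true(all(af$values > 0 & af$values <= 1))
  expect_true(all(af2$values <= af$values + 1e-12))
})
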