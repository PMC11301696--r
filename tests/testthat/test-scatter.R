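test_that("degenerate inputs give zero scatter without error", {
  g <- tiny_geometry(); grid <- tiny_grid()
  ph <- tiny_phantom(grid)
  zeroact <- volume_image(array(0, c(32, 32, 4)), grid, "activity")
  expect_identical(sum(estimate_scatter_2d(zeroact, ph$attenuation, g,
                                           scatter_config(), 2)), 0)
  zeromu <- volume_image(array(0, c(32, 32, 4)), grid, "attenuation")
  expect_identical(sum(estimate_scatter_2d(ph$activity, zeromu, g,
                                           scatter_config(), 2)), 0)
})

test_that("scatter from a central point source is smooth and much wider
           than the trues", {
  g <- scanner_geometry("sc", ring_radius_mm = 300, n_projections = 64,
                        n_views = 8, n_planes = 1, span = 1, n_tof_bins = 1,
                        tof_bin_width_ps = 100, timing_resolution_ps = 200,
                        fov_transaxial_mm = 256, fov_axial_mm = 4)
  grid <- voxel_grid(64, 64, 1, 4, 4, 4)
  spec <- phantom_spec(list(
    shape("cylinder", c(0, 0, 0), c(100, 10), activity = 0,
          attenuation = 0.096),
    shape("sphere", c(0, 0, 0), 9, activity = 1000, attenuation = 0.096)))
  act <- rasterize(spec, grid, 3, "activity")
  mu <- rasterize(spec, grid, 3, "attenuation")
  sc <- estimate_scatter_2d(act, mu, g, scatter_config(), 1)
  expect_true(all(sc >= 0))
  expect_gt(sum(sc), 0)
  trues <- forward_project(act, g)$values[, 1, 1]
  prof <- sc[, 1]
  expect_gt(measure_fwhm(prof, 1) / measure_fwhm(trues, 1), 2)
  # radial power above Nyquist/4 is a small fraction of the total
  spec_pow <- Mod(stats::fft(prof - mean(prof)))^2
  n <- length(prof)
  hi <- ceiling(n / 8):(n - floor(n / 8))   # |freq| > Nyquist/4
  expect_lt(sum(spec_pow[hi]) / sum(spec_pow), 0.10)
})

test_that("inverse single-slice rebinning interpolates between slices", {
  g <- scanner_geometry("ssrb", ring_radius_mm = 200, n_projections = 8,
                        n_views = 4, n_planes = 15, span = 1, n_tof_bins = 1,
                        tof_bin_width_ps = 100, timing_resolution_ps = 200,
                        fov_transaxial_mm = 128, fov_axial_mm = 60)
  # identical slices -> every plane identical
  grid5 <- voxel_grid(8, 8, 5, 16, 16, 12)
  one <- matrix(stats::runif(8 * 4), 8, 4)
  same <- array(rep(one, 5), c(8, 4, 5))
  s3 <- inverse_ssrb(same, g, grid5)
  for (p in seq_len(15)) expect_equal(s3$values[, , p], one)
  # two distinct slices: the midway plane equals their average
  grid2 <- voxel_grid(8, 8, 2, 16, 16, 30)
  a <- matrix(1, 8, 4); b <- matrix(3, 8, 4)
  s2 <- inverse_ssrb(array(c(a, b), c(8, 4, 2)), g, grid2)
  expect_equal(s2$values[, , 8], (a + b) / 2)   # middle plane sits at z = 0
  # axially linear ramp reproduced by per-plane totals (interior planes)
  gridr <- voxel_grid(8, 8, 5, 16, 16, 12)
  ramp <- array(rep(1:5, each = 8 * 4), c(8, 4, 5))
  sr <- inverse_ssrb(ramp, g, gridr)
  zp <- petsim:::plane_z_positions(g)
  zs <- gridr$origin[3] + (0:4) * 12
  interior <- zp >= zs[1] & zp <= zs[5]
  expected <- 8 * 4 * (1 + (zp - zs[1]) / 12)
  tot <- apply(sr$values, 3, sum)
  expect_lt(max(abs(tot[interior] - expected[interior]) /
                  expected[interior]), 0.005)
  expect_error(inverse_ssrb(array(0, c(8, 4, 0)), g, grid5), "empty")
})

test_that("scatter scaling hits the target fraction exactly", {
  g <- tiny_geometry()
  set.seed(5)
  sc <- sinogram(array(stats::runif(48 * 24 * 4), c(48, 24, 4)), g)
  tr <- sinogram(array(stats::runif(48 * 24 * 4) * 7e6 / (48 * 24 * 4) * 2,
                       c(48, 24, 4)), g)
  tr$values <- tr$values * (7e6 / sum(tr$values))
  out <- scale_scatter(sc, tr, scatter_config(scatter_fraction_target = 0.3))
  expect_equal(sum(out$values), 3e6, tolerance = 1e-12)
  expect_equal(sum(out$values) / (sum(out$values) + sum(tr$values)), 0.3,
               tolerance = 1e-12)
  # shape preserved: one global constant
  ratio <- out$values / sc$values
  expect_lt(diff(range(ratio)), 1e-12 * mean(ratio))
  # small fractions give (near) zero scatter
  tiny <- scale_scatter(sc, tr, scatter_config(scatter_fraction_target = 1e-9))
  expect_lt(sum(tiny$values) / sum(tr$values), 1e-8)
  # absolute mode returns unscaled
  abs_out <- scale_scatter(sc, tr,
                           scatter_config(scatter_fraction_target = "absolute"))
  expect_identical(abs_out$values, sc$values)
  expect_error(scatter_config(scatter_fraction_target = 1.2), "\\(0, 1\\)")
})
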