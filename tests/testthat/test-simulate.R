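test_that("pre-smoothing is identity at 0, conserves counts, and hits the
           nominal impulse-response width", {
  grid <- voxel_grid(61, 61, 61, 1, 1, 1)
  arr <- array(0, c(61, 61, 61)); arr[31, 31, 31] <- 1
  img <- volume_image(arr, grid, "activity")
  expect_identical(presmooth(img, 0)$values, arr)
  sm <- presmooth(img, 3)
  expect_lt(abs(sum(sm$values) - 1), 1e-6)
  fw <- c(measure_fwhm(sm$values[, 31, 31], 1),
          measure_fwhm(sm$values[31, , 31], 1),
          measure_fwhm(sm$values[31, 31, ], 1))
  expect_true(all(abs(fw - 3) <= 0.2))
  # anisotropic voxels: kernel is isotropic in mm
  grid2 <- voxel_grid(61, 61, 41, 1.65, 1.65, 1.646)
  arr2 <- array(0, c(61, 61, 41)); arr2[31, 31, 21] <- 1
  sm2 <- presmooth(volume_image(arr2, grid2, "activity"), 3)
  expect_lt(abs(measure_fwhm(sm2$values[, 31, 21], 1.65) - 3), 0.2)
})

test_that("sensitivity and random-rate calibration identities are exact", {
  g <- tiny_geometry(); grid <- tiny_grid()
  # non-attenuated 100 kBq source, T = 10 s -> exactly 38 cps/kBq
  act <- array(0, c(32, 32, 4))
  act[14:18, 14:18, 2:3] <- 1
  act <- act * (100e3 / (sum(act) * petsim:::voxel_volume_ml(grid)))
  activity <- volume_image(act, grid, "activity")
  mu0 <- volume_image(array(0, c(32, 32, 4)), grid, "attenuation")
  cfg <- simulation_config(10, scatter = "off", seed = 1)
  set <- simulate_noise_free(activity, mu0, g, cfg)
  expect_equal(set$counts$trues / (100 * 10), 38, tolerance = 1e-9)
  expect_equal(set$counts$randoms / set$counts$trues, 0.20,
               tolerance = 1e-12)
  # linearity in T, S and global activity scale
  cfg2 <- cfg; cfg2$acquisition_time_s <- 25
  expect_equal(simulate_noise_free(activity, mu0, g, cfg2)$counts$trues,
               set$counts$trues * 2.5, tolerance = 1e-9)
  cfg3 <- cfg; cfg3$sensitivity_cps_per_kbq <- 76
  expect_equal(simulate_noise_free(activity, mu0, g, cfg3)$counts$trues,
               set$counts$trues * 2, tolerance = 1e-9)
  double <- volume_image(act * 2, grid, "activity")
  expect_equal(simulate_noise_free(double, mu0, g, cfg)$counts$trues,
               set$counts$trues * 2, tolerance = 1e-9)
  # zero activity -> all components zero
  z <- volume_image(array(0, c(32, 32, 4)), grid, "activity")
  setz <- simulate_noise_free(z, mu0, g, cfg)
  expect_identical(setz$counts$trues + setz$counts$randoms +
                     setz$counts$scatter, 0)
})

test_that("TOF simulation: delayed window total equals r x trues exactly", {
  g <- tiny_geometry(); grid <- tiny_grid()
  ph <- tiny_phantom(grid)
  cfg <- simulation_config(5, scatter = "off", tof = TRUE, seed = 3)
  set <- simulate_noise_free(ph$activity, ph$attenuation, g, cfg)
  delayed <- apply(set$randoms$values, 1:3, sum)
  expect_equal(sum(delayed), 0.20 * set$counts$trues, tolerance = 1e-9)
  # noise-free prompts are the bin-wise sum of the three components
  expect_true(set$trues$tof && set$randoms$tof)
})

test_that("denormalization divides bin-wise and is the identity for the
           uniform default", {
  g <- tiny_geometry()
  set.seed(2)
  s <- sinogram(array(stats::runif(48 * 24 * 4), c(48, 24, 4)), g)
  expect_identical(denormalize(s, "uniform")$values, s$values)
  norm2 <- sinogram(array(2, c(48, 24, 4)), g)
  expect_equal(denormalize(s, norm2)$values, s$values / 2)
  # round trip with the recon-side multiplication
  back <- denormalize(s, norm2)$values * norm2$values
  expect_lt(max(abs(back - s$values)), 1e-12)
  bad <- sinogram(array(0, c(48, 24, 4)), g)
  expect_error(denormalize(s, bad), "zero")
})

test_that("Poisson noise has the right mean, dispersion and reproducibility", {
  g <- scanner_geometry("noise", ring_radius_mm = 200, n_projections = 16,
                        n_views = 8, n_planes = 2, span = 1, n_tof_bins = 1,
                        tof_bin_width_ps = 100, timing_resolution_ps = 200,
                        fov_transaxial_mm = 100, fov_axial_mm = 8)
  grid <- voxel_grid(16, 16, 2, 6.25, 6.25, 4)
  set.seed(11)
  act <- volume_image(array(stats::runif(16 * 16 * 2) * 5000,
                            c(16, 16, 2)), grid, "activity")
  mu0 <- volume_image(array(0, c(16, 16, 2)), grid, "attenuation")
  cfg <- simulation_config(30, scatter = "off", seed = 123,
                           n_realizations = 200)
  set <- simulate_noise_free(act, mu0, g, cfg)
  set <- add_noise(set, g, cfg)
  lam <- set$trues$values + set$scatter$values + set$randoms$values
  # mean check: 200-realization average of totals within 3 SE
  se <- sqrt(sum(lam) / 200)
  expect_lt(abs(mean(set$counts$prompts) - sum(lam)), 3 * se)
  # index of dispersion aggregated over bins with mean > 10
  stack <- vapply(set$prompts_noisy, function(s) s$values, lam)
  mbin <- apply(stack, 1:3, mean)
  vbin <- apply(stack, 1:3, stats::var)
  idx <- mbin > 10
  disp <- mean(vbin[idx] / mbin[idx])
  expect_gt(disp, 0.9); expect_lt(disp, 1.1)
  # same seed -> bit-identical realization; different -> different
  cfg1 <- cfg; cfg1$n_realizations <- 1
  a <- add_noise(set, g, cfg1)$prompts_noisy[[1]]$values
  b <- add_noise(set, g, cfg1)$prompts_noisy[[1]]$values
  expect_identical(a, b)
  cfg2 <- cfg1; cfg2$seed <- 999L
  expect_false(identical(a, add_noise(set, g, cfg2)$prompts_noisy[[1]]$values))
})

test_that("sensitivity calibration closed form round-trips and scales", {
  g <- tiny_geometry(); grid <- tiny_grid()
  ph <- tiny_phantom(grid)
  cfg <- simulation_config(600, scatter = "off", seed = 1)
  set <- simulate_noise_free(ph$activity, ph$attenuation, g, cfg)
  S <- calibrate_sensitivity(set$counts$trues, ph$activity, ph$attenuation,
                             g, cfg)
  expect_equal(S, 38, tolerance = 1e-9)
  expect_equal(calibrate_sensitivity(2 * set$counts$trues, ph$activity,
                                     ph$attenuation, g, cfg), 76,
               tolerance = 1e-9)
  # time-invariance: the same phantom observed for 1 min gives the same S
  cfg1 <- cfg; cfg1$acquisition_time_s <- 60
  set1 <- simulate_noise_free(ph$activity, ph$attenuation, g, cfg1)
  expect_equal(calibrate_sensitivity(set1$counts$trues, ph$activity,
                                     ph$attenuation, g, cfg1), 38,
               tolerance = 1e-9)
  expect_error(calibrate_sensitivity(0, ph$activity, ph$attenuation, g, cfg),
               "> 0")
})

test_that("pre-smoothing grid search recovers the generating FWHM", {
  geom <- make_scaled_geometry(0.2)
  cfg <- simulation_config(60, scatter = "off", seed = 4)
  rcfg <- recon_config(2, 2, geom$grid)
  ctx <- list(geometry = geom$geometry, grid = geom$grid, config = cfg,
              recon = rcfg)
  ref <- suppressWarnings(
    petsim:::nema_noise_free_rc(geom$geometry, geom$grid, cfg, rcfg, 3))
  res <- suppressWarnings(calibrate_presmooth(ref, c(1, 3, 5), ctx))
  expect_equal(res$best_fwhm_mm, 3)
  expect_equal(nrow(res$objective), 3)        # audit trail for every candidate
  expect_equal(min(res$objective$objective),
               res$objective$objective[res$objective$fwhm_mm == 3])
  single <- suppressWarnings(calibrate_presmooth(ref, 2, ctx))
  expect_equal(single$best_fwhm_mm, 2)
  expect_error(calibrate_presmooth(ref, numeric(0), ctx), "empty")
})
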