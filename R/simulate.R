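# Acquisition simulation: pre-smoothing, projection, attenuation,
# sensitivity scaling, randoms, scatter, denormalization, delayed window,
# Poisson noise, and the calibration procedures.

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

gaussian_smooth_1d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  k <- gaussian_kernel_1d(sigma)
  r <- (length(k) - 1L) / 2L
  n <- length(x)
  out <- numeric(n)
  for (m in seq_along(k)) {
    off <- m - r - 1L
    dst <- max(1L, 1L - off):min(n, n - off)
    if (dst[1] > dst[length(dst)]) next
    out[dst] <- out[dst] + k[m] * x[dst + off]
  }
  out
}

# Separable 3D Gaussian smoothing; sigma per axis in voxels.
gaussian_smooth_3d <- function(a, sigma_vox) {
  dims <- dim(a)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    k <- gaussian_kernel_1d(s)
    r <- (length(k) - 1L) / 2L
    n <- dims[axis]
    out <- array(0, dims)
    for (m in seq_along(k)) {
      off <- m - r - 1L
      dst <- max(1L, 1L - off):min(n, n - off)
      if (dst[1] > dst[length(dst)]) next
      src <- dst + off
      if (axis == 1) out[dst, , ] <- out[dst, , ] + k[m] * a[src, , ]
      else if (axis == 2) out[, dst, ] <- out[, dst, ] + k[m] * a[, src, ]
      else out[, , dst] <- out[, , dst] + k[m] * a[, , src]
    }
    a <- out
  }
  a
}

#' Simulation configuration
#'
#' @param acquisition_time_s Acquisition time T in seconds (> 0).
#' @param sensitivity_cps_per_kbq Scanner sensitivity S in counts per second
#'   per kBq (default 38, the calibrated value for the reference scanner).
#' @param random_rate Randoms-to-trues ratio r (default 0.20, calibrated).
#' @param presmooth_fwhm_mm FWHM (mm) of the isotropic pre-smoothing
#'   Gaussian emulating intrinsic system resolution (default 3.0,
#'   calibrated).
#' @param tof Logical, carry a TOF dimension through the simulation.
#' @param scatter A [scatter_config], or `"off"` to skip scatter.
#' @param normalization `"uniform"` (identity denormalization) or a
#'   normalization [sinogram].
#' @param seed Master integer seed; noise realization `i` uses `seed + i`.
#' @param n_realizations Number of independent noise realizations.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(acquisition_time_s,
                              sensitivity_cps_per_kbq = 38,
                              random_rate = 0.20,
                              presmooth_fwhm_mm = 3.0,
                              tof = FALSE,
                              scatter = scatter_config(),
                              normalization = "uniform",
                              seed = 1,
                              n_realizations = 1) {
  if (acquisition_time_s <= 0) stop("acquisition time must be > 0")
  if (sensitivity_cps_per_kbq <= 0) stop("sensitivity must be > 0")
  if (random_rate < 0) stop("random rate must be >= 0")
  if (presmooth_fwhm_mm < 0) stop("pre-smoothing FWHM must be >= 0")
  if (n_realizations < 1) stop("n_realizations must be >= 1")
  structure(list(acquisition_time_s = acquisition_time_s,
                 sensitivity_cps_per_kbq = sensitivity_cps_per_kbq,
                 random_rate = random_rate,
                 presmooth_fwhm_mm = presmooth_fwhm_mm,
                 tof = tof, scatter = scatter,
                 normalization = normalization,
                 seed = as.integer(seed),
                 n_realizations = as.integer(n_realizations)),
            class = "simulation_config")
}

#' Pre-smoothing of the activity map
#'
#' 3D isotropic Gaussian convolution emulating the intrinsic spatial
#' resolution of the system (positron range, photon non-collinearity,
#' detector resolution); `sigma = fwhm / (2 sqrt(2 log 2))`, expressed per
#' axis in voxels from the grid's edge lengths. The total is renormalized
#' after convolution so activity is conserved even near the grid edges.
#'
#' @param activity A [volume_image].
#' @param fwhm_mm Kernel FWHM in mm (0 = identity).
#' @return A [volume_image].
#' @export
presmooth <- function(activity, fwhm_mm) {
  if (fwhm_mm < 0) stop("fwhm must be >= 0")
  if (fwhm_mm == 0) return(activity)
  sig <- fwhm_mm / (2 * sqrt(2 * log(2))) / grid_sizes(activity$grid)
  out <- gaussian_smooth_3d(activity$values, sig)
  tot_in <- sum(activity$values); tot_out <- sum(out)
  if (tot_out > 0) out <- out * (tot_in / tot_out)
  volume_image(out, activity$grid, activity$quantity)
}

zero_like <- function(s) sinogram(array(0, dim(s$values)), s$geometry, s$tof)

# Broadcast a non-TOF sinogram array over the TOF dimension of dims.
expand_tof <- function(a3, ntof) array(a3, c(dim(a3), ntof))

#' Noise-free acquisition simulation
#'
#' Runs the noise-free part of the pipeline: the activity map (Bq/ml) is
#' pre-smoothed, converted to decays per voxel (`value * voxel_volume_ml *
#' T`), forward projected with the counts-preserving projector, attenuated,
#' and scaled by the sensitivity expressed as counts per decay (`S / 1000`
#' for S in cps/kBq) -- so for a non-attenuated source the total trues are
#' exactly `S * T * A_kBq`. Randoms are uniform in projection space with
#' `sum(randoms) = r * sum(trues)`; scatter follows the single-scatter
#' model scaled to the configured fraction. All components pass through
#' [denormalize()].
#'
#' @param activity,mu [volume_image]s on a shared grid.
#' @param g A [scanner_geometry].
#' @param cfg A [simulation_config].
#' @return An object of class `sinogram_set` with noise-free `trues`,
#'   `scatter`, `randoms`, empty `prompts_noisy` / `delayed_noisy` lists and
#'   a `counts` record.
#' @export
simulate_noise_free <- function(activity, mu, g, cfg) {
  if (!identical(grid_counts(activity$grid), grid_counts(mu$grid)))
    stop("activity and attenuation maps must share a grid")
  if (cfg$acquisition_time_s <= 0) stop("acquisition time must be > 0")
  grid <- activity$grid
  sm <- presmooth(activity, cfg$presmooth_fwhm_mm)
  decays <- volume_image(sm$values * voxel_volume_ml(grid) *
                           cfg$acquisition_time_s, grid, "activity")
  s_per_decay <- cfg$sensitivity_cps_per_kbq / 1000
  proj <- forward_project(decays, g, tof = cfg$tof)
  attn <- attenuation_factors(mu, g)
  att_arr <- if (cfg$tof) expand_tof(attn$values, g$n_tof_bins)
             else attn$values
  trues <- sinogram(proj$values * att_arr * s_per_decay, g, tof = cfg$tof)
  tot_t <- sum(trues$values)
  rnd_val <- cfg$random_rate * tot_t / length(trues$values)
  randoms <- sinogram(array(rnd_val, dim(trues$values)), g, tof = cfg$tof)
  if (identical(cfg$scatter, "off") || is.null(cfg$scatter)) {
    scat <- zero_like(trues)
  } else {
    slices <- vapply(seq_len(grid$nz), function(k)
      estimate_scatter_2d(sm, mu, g, cfg$scatter, k),
      matrix(0, g$n_projections, g$n_views))
    sc3 <- inverse_ssrb(slices, g, grid)
    trues_nontof <- if (cfg$tof)
      sinogram(apply(trues$values, 1:3, sum), g, tof = FALSE) else trues
    sc3 <- scale_scatter(sc3, trues_nontof, cfg$scatter)
    scat <- if (cfg$tof)
      sinogram(expand_tof(sc3$values / g$n_tof_bins, g$n_tof_bins), g,
               tof = TRUE)
    else sc3
  }
  trues <- denormalize(trues, cfg$normalization)
  randoms <- denormalize(randoms, cfg$normalization)
  scat <- denormalize(scat, cfg$normalization)
  structure(list(trues = trues, scatter = scat, randoms = randoms,
                 prompts_noisy = list(), delayed_noisy = list(),
                 counts = list(trues = sum(trues$values),
                               scatter = sum(scat$values),
                               randoms = sum(randoms$values),
                               prompts = numeric(0)),
                 geometry = g, grid = grid, config = cfg),
            class = "sinogram_set")
}

#' @export
format.sinogram_set <- function(x, ...) {
  sprintf("sinogram_set: trues %.6g, scatter %.6g, randoms %.6g, %d noisy",
          x$counts$trues, x$counts$scatter, x$counts$randoms,
          length(x$prompts_noisy))
}

#' @export
print.sinogram_set <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Denormalization
#'
#' Bin-wise division by a normalization sinogram (geometric efficiency
#' variations). With the `"uniform"` default this is the identity:
#' component-based normalization cancels between simulation and
#' reconstruction when it is uniform.
#'
#' @param s A [sinogram].
#' @param normalization `"uniform"` or a [sinogram] with strictly nonzero
#'   bins.
#' @return A [sinogram].
#' @export
denormalize <- function(s, normalization = "uniform") {
  if (identical(normalization, "uniform")) return(s)
  nv <- normalization$values
  if (any(nv == 0)) stop("normalization sinogram contains zero bins")
  arr <- if (s$tof && length(dim(nv)) == 3)
    s$values / expand_tof(nv, dim(s$values)[4]) else s$values / nv
  sinogram(arr, s$geometry, s$tof)
}

#' Add Poisson noise realizations
#'
#' For realization `i` (seeded with `cfg$seed + i`) the noisy prompts are
#' element-wise Poisson draws from `trues + scatter + randoms`, and the
#' noisy delayed-window bin is an independent Poisson draw from the randoms
#' summed over the TOF dimension (or the randoms themselves without TOF),
#' matching a physically acquired delayed window.
#'
#' @param set A `sinogram_set` from [simulate_noise_free()].
#' @param g A [scanner_geometry].
#' @param cfg A [simulation_config].
#' @return The `sinogram_set` with `prompts_noisy` and `delayed_noisy`
#'   filled (one [sinogram] per realization) and per-realization prompt
#'   totals in `counts$prompts`.
#' @export
add_noise <- function(set, g, cfg = set$config) {
  lam <- set$trues$values + set$scatter$values + set$randoms$values
  if (any(lam < 0)) stop("negative noise-free bins")
  lam_del <- if (set$randoms$tof) apply(set$randoms$values, 1:3, sum)
             else set$randoms$values
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  prompts <- vector("list", cfg$n_realizations)
  delayed <- vector("list", cfg$n_realizations)
  totals <- numeric(cfg$n_realizations)
  for (i in seq_len(cfg$n_realizations)) {
    set.seed(cfg$seed + i)
    p <- array(stats::rpois(length(lam), lam), dim(lam))
    d <- array(stats::rpois(length(lam_del), lam_del), dim(lam_del))
    prompts[[i]] <- sinogram(p, g, tof = set$trues$tof)
    delayed[[i]] <- sinogram(d, g, tof = FALSE)
    totals[i] <- sum(p)
  }
  set$prompts_noisy <- prompts
  set$delayed_noisy <- delayed
  set$counts$prompts <- totals
  set
}

#' Calibrate the sensitivity against observed true counts
#'
#' True counts are exactly linear in the sensitivity, so the calibrated S is
#' obtained in closed form from a single unit-sensitivity simulation.
#'
#' @param observed_true_counts Total true events measured on the scanner
#'   (> 0).
#' @param activity,mu [volume_image]s describing the calibration phantom.
#' @param g A [scanner_geometry].
#' @param cfg A [simulation_config] (its sensitivity value is ignored).
#' @return Sensitivity S in cps/kBq.
#' @export
calibrate_sensitivity <- function(observed_true_counts, activity, mu, g,
                                  cfg) {
  if (observed_true_counts <= 0) stop("observed true counts must be > 0")
  cfg$sensitivity_cps_per_kbq <- 1
  cfg$scatter <- "off"
  base <- simulate_noise_free(activity, mu, g, cfg)
  t1 <- base$counts$trues
  if (t1 <= 0) stop("attenuated projection of the phantom is zero")
  observed_true_counts / t1
}

#' Grid-search calibration of the pre-smoothing FWHM
#'
#' Simulates and reconstructs the image-quality phantom for each candidate
#' FWHM and returns the candidate minimizing the sum of squared differences
#' between the resulting sphere recovery coefficients and a reference set.
#' Noise-free and deterministic.
#'
#' @param reference_rc Reference recovery coefficients, one per sphere
#'   (values in (0, 1.5]).
#' @param fwhm_grid_mm Candidate FWHM values (mm).
#' @param context List with `geometry`, `grid`, `config` (a
#'   [simulation_config]) and `recon` (a [recon_config]).
#' @return List with `best_fwhm_mm`, and `objective` -- a data.frame
#'   reporting the objective for every candidate (audit trail).
#' @export
calibrate_presmooth <- function(reference_rc, fwhm_grid_mm, context) {
  if (!length(fwhm_grid_mm)) stop("empty FWHM grid")
  if (any(reference_rc <= 0) || any(reference_rc > 1.5))
    stop("reference RCs must lie in (0, 1.5]")
  obj <- numeric(length(fwhm_grid_mm))
  for (k in seq_along(fwhm_grid_mm)) {
    rc <- nema_noise_free_rc(context$geometry, context$grid, context$config,
                             context$recon, fwhm_grid_mm[k])
    obj[k] <- sum((rc - reference_rc)^2)
  }
  list(best_fwhm_mm = fwhm_grid_mm[which.min(obj)],
       objective = data.frame(fwhm_mm = fwhm_grid_mm, objective = obj))
}

# Noise-free NEMA simulation + reconstruction -> sphere RCs (helper shared
# by the FWHM calibration and the experiments).
nema_noise_free_rc <- function(g, grid, cfg, rcfg, fwhm_mm = NULL) {
  if (!is.null(fwhm_mm)) cfg$presmooth_fwhm_mm <- fwhm_mm
  nema <- make_nema_iq(grid)
  set <- simulate_noise_free(nema$activity, nema$attenuation, g, cfg)
  prompts_nf <- sinogram(set$trues$values + set$scatter$values +
                           set$randoms$values, g, tof = cfg$tof)
  attn <- attenuation_factors(nema$attenuation, g)
  img <- op_osem(prompts_nf, set$randoms, set$scatter, attn, g, rcfg)
  act <- counts_to_activity(img, cfg)
  rois <- nema_rois(grid, nema$spec)
  vapply(seq_along(nema$spec$sphere_diameters_mm), function(k)
    recovery_coefficient(act, rois$spheres[[k]], nema$spec$sphere_conc),
    numeric(1))
}

#' Convert a reconstructed counts image back to activity concentration
#'
#' The reconstruction operates in the decay-counts domain of the simulation;
#' dividing by `voxel_volume_ml * T * S/1000` returns Bq/ml.
#'
#' @param img Reconstructed [volume_image].
#' @param cfg The [simulation_config] used for the acquisition.
#' @return A [volume_image] (quantity `"reconstructed"`) in Bq/ml.
#' @export
counts_to_activity <- function(img, cfg) {
  f <- voxel_volume_ml(img$grid) * cfg$acquisition_time_s *
    cfg$sensitivity_cps_per_kbq / 1000
  volume_image(img$values / f, img$grid, "reconstructed")
}
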