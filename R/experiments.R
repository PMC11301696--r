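# End-to-end experiment drivers: the NEMA image-quality analysis and the
# two-simulation feature/segmentation concordance analysis.

merge_defaults <- function(config, defaults) {
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  config
}

scale_set <- function(base, T) {
  s <- base
  s$trues <- sinogram(base$trues$values * T, base$geometry, base$trues$tof)
  s$scatter <- sinogram(base$scatter$values * T, base$geometry,
                        base$scatter$tof)
  s$randoms <- sinogram(base$randoms$values * T, base$geometry,
                        base$randoms$tof)
  s$counts <- list(trues = sum(s$trues$values),
                   scatter = sum(s$scatter$values),
                   randoms = sum(s$randoms$values), prompts = numeric(0))
  s
}

#' NEMA image-quality experiment
#'
#' Simulates the image-quality phantom at each requested acquisition time,
#' reconstructs all noise realizations plus a matched noise-free run, and
#' assembles the recovery-coefficient and background-variability analysis:
#' RC per sphere (mean, SD and noise-free reference), COV per ROI versus
#' acquisition time, voxelwise mean/STD maps and Freedman-Diaconis
#' histograms at the shortest and longest times. All noise-free components
#' are exactly linear in the acquisition time, so the pipeline is simulated
#' once and rescaled per time point.
#'
#' @param config Named list; recognized fields (with defaults):
#'   `geometry_scale` (0.25), `times` (c(5, 10, 30, 60, 120) s),
#'   `n_realizations` (5), `seed` (1), `sensitivity_cps_per_kbq` (38),
#'   `random_rate` (0.2), `presmooth_fwhm_mm` (3), `scatter`
#'   ([scatter_config()] or `"off"`), `iterations` (8), `subsets` (5),
#'   `psf_fwhm_mm` (0), `postfilter_fwhm_mm` (0), `out` (optional directory
#'   for the manifest).
#' @return A report list: `rc_mean`, `rc_sd`, `rc_noise_free` (6 x n_times
#'   matrices), `cov` ((6 + 1) x n_times, background last), `mean_maps`,
#'   `std_maps`, `histograms`, `manifest`.
#' @export
run_nema_experiment <- function(config = list()) {
  config <- merge_defaults(config, list(
    geometry_scale = 0.25, times = c(5, 10, 30, 60, 120),
    n_realizations = 5, seed = 1, sensitivity_cps_per_kbq = 38,
    random_rate = 0.2, presmooth_fwhm_mm = 3, scatter = scatter_config(),
    iterations = 8, subsets = 5, psf_fwhm_mm = 0, postfilter_fwhm_mm = 0,
    out = NULL))
  t0 <- Sys.time(); stage_s <- c()
  geom <- make_scaled_geometry(config$geometry_scale)
  g <- geom$geometry; grid <- geom$grid
  nema <- make_nema_iq(grid)
  rois <- nema_rois(grid, nema$spec)
  diam <- nema$spec$sphere_diameters_mm
  stage_s["phantom"] <- as.numeric(Sys.time() - t0, units = "secs")
  cfg1 <- simulation_config(acquisition_time_s = 1,
                            sensitivity_cps_per_kbq =
                              config$sensitivity_cps_per_kbq,
                            random_rate = config$random_rate,
                            presmooth_fwhm_mm = config$presmooth_fwhm_mm,
                            scatter = config$scatter, seed = config$seed,
                            n_realizations = config$n_realizations)
  t1 <- Sys.time()
  base <- simulate_noise_free(nema$activity, nema$attenuation, g, cfg1)
  attn <- attenuation_factors(nema$attenuation, g)
  stage_s["simulate"] <- as.numeric(Sys.time() - t1, units = "secs")
  rcfg <- recon_config(config$iterations, config$subsets, grid,
                       psf_fwhm_mm = config$psf_fwhm_mm,
                       postfilter_fwhm_mm = config$postfilter_fwhm_mm)
  nt <- length(config$times)
  rc_mean <- rc_sd <- rc_nf <- matrix(NA_real_, 6, nt,
                                      dimnames = list(names(rois$spheres),
                                                      config$times))
  covm <- matrix(NA_real_, 7, nt,
                 dimnames = list(c(names(rois$spheres), "background"),
                                 config$times))
  seeds_used <- list()
  counts <- list()
  mean_maps <- list(); std_maps <- list(); histograms <- list()
  t2 <- Sys.time()
  for (ti in seq_len(nt)) {
    T <- config$times[ti]
    cfgT <- cfg1
    cfgT$acquisition_time_s <- T
    cfgT$seed <- as.integer(config$seed + 1000 * (ti - 1))
    setT <- scale_set(base, T)
    setT$config <- cfgT
    setT <- add_noise(setT, g, cfgT)
    seeds_used[[as.character(T)]] <- cfgT$seed + seq_len(cfgT$n_realizations)
    counts[[as.character(T)]] <- setT$counts
    imgs <- lapply(seq_len(cfgT$n_realizations), function(i) {
      rec <- op_osem(setT$prompts_noisy[[i]], setT$delayed_noisy[[i]],
                     setT$scatter, attn, g, rcfg)
      counts_to_activity(rec, cfgT)
    })
    prompts_nf <- sinogram(setT$trues$values + setT$scatter$values +
                             setT$randoms$values, g, tof = cfgT$tof)
    img_nf <- counts_to_activity(
      op_osem(prompts_nf, setT$randoms, setT$scatter, attn, g, rcfg), cfgT)
    for (k in 1:6) {
      rcs <- vapply(imgs, recovery_coefficient, numeric(1),
                    roi = rois$spheres[[k]],
                    true_value = nema$spec$sphere_conc)
      rc_mean[k, ti] <- mean(rcs)
      rc_sd[k, ti] <- stats::sd(rcs)
      rc_nf[k, ti] <- recovery_coefficient(img_nf, rois$spheres[[k]],
                                           nema$spec$sphere_conc)
      covm[k, ti] <- mean(vapply(imgs, roi_cov, numeric(1),
                                 roi = rois$spheres[[k]]))
    }
    covm[7, ti] <- mean(vapply(imgs, roi_cov, numeric(1),
                               roi = rois$background))
    if (ti == 1 || ti == nt) {
      ms <- voxelwise_mean_std(imgs)
      key <- as.character(T)
      mean_maps[[key]] <- ms$mean
      std_maps[[key]] <- ms$std
      histograms[[key]] <- list(
        background_mean = fd_histogram(ms$mean$values[rois$background]),
        background_std = fd_histogram(ms$std$values[rois$background]),
        spheres_mean = fd_histogram(
          ms$mean$values[Reduce(`|`, rois$spheres)]))
    }
  }
  stage_s["reconstruct_analyze"] <- as.numeric(Sys.time() - t2,
                                               units = "secs")
  manifest <- list(experiment = "nema_iq",
                   config = config[setdiff(names(config), "scatter")],
                   scatter = if (identical(config$scatter, "off")) "off"
                             else unclass(config$scatter),
                   geometry_preset = g$name, seeds = seeds_used,
                   counts = counts, stage_seconds = as.list(stage_s))
  if (!is.null(config$out)) {
    dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
    write_manifest(manifest, file.path(config$out, "manifest.json"))
    rc_tab <- data.frame(diameter_mm = diam, rc_mean, check.names = FALSE)
    utils::write.csv(rc_tab, file.path(config$out, "rc_vs_diameter.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(roi = rownames(covm), covm,
                                check.names = FALSE),
                     file.path(config$out, "cov_vs_time.csv"),
                     row.names = FALSE)
  }
  list(rc_mean = rc_mean, rc_sd = rc_sd, rc_noise_free = rc_nf, cov = covm,
       sphere_diameters_mm = diam, mean_maps = mean_maps,
       std_maps = std_maps, histograms = histograms, manifest = manifest)
}

# Lesion mask by fractional-peak auto-thresholding within a local search
# sphere (a stand-in for manual delineation, labeled as such in reports).
threshold_lesion_mask <- function(img, center, diameter, fraction = 0.4) {
  region <- sphere_mask(img$grid, center, 2 * diameter)
  peak <- max(img$values[region])
  region & img$values >= fraction * peak
}

#' Two-simulation feature and segmentation concordance experiment
#'
#' Simulates the synthetic torso twice (two noise seeds), reconstructs both,
#' computes the ten intensity/texture features per organ and lesion ROI on
#' both images, regresses the feature sets against each other, derives
#' lesion masks on both images by fractional-peak auto-thresholding (a
#' stand-in for human delineation), and reports overlap metrics, shape
#' features and Lin's CCC across lesions.
#'
#' @param config Named list; recognized fields (with defaults):
#'   `geometry_scale` (0.25), `time_s` (300), `seeds` (c(1, 2)),
#'   `phantom_seed` (42), `lesions` (two lesions in liver and lung),
#'   `threshold_fraction` (0.4), `iterations` (4), `subsets` (5),
#'   `scatter` ([scatter_config()] or `"off"`), `glcm_bin_width` (100
#'   Bq/ml), `out` (optional directory).
#' @return A report list: `features` (per ROI x feature x variant),
#'   `feature_comparison` (per feature regression/correlation), `overlap`
#'   (per lesion), `shape` (per lesion x variant), `shape_ccc`, `manifest`.
#' @export
run_concordance_experiment <- function(config = list()) {
  config <- merge_defaults(config, list(
    geometry_scale = 0.25, time_s = 300, seeds = c(1, 2), phantom_seed = 42,
    lesions = list(list(center = c(55, -20, -50), diameter = 33, uptake = 3),
                   list(center = c(-65, 15, 35), diameter = 26, uptake = 8)),
    threshold_fraction = 0.4, iterations = 4, subsets = 5,
    scatter = scatter_config(), glcm_bin_width = 100, out = NULL))
  if (!length(config$lesions)) stop("need at least one lesion")
  t0 <- Sys.time(); stage_s <- c()
  geom <- make_scaled_geometry(config$geometry_scale)
  g <- geom$geometry; grid <- geom$grid
  torso <- make_synthetic_torso(grid, seed = config$phantom_seed,
                                lesions = config$lesions)
  stage_s["phantom"] <- as.numeric(Sys.time() - t0, units = "secs")
  rcfg <- recon_config(config$iterations, config$subsets, grid)
  attn <- attenuation_factors(torso$attenuation, g)
  t1 <- Sys.time()
  imgs <- lapply(config$seeds, function(sd) {
    cfg <- simulation_config(acquisition_time_s = config$time_s,
                             scatter = config$scatter, seed = sd,
                             n_realizations = 1)
    set <- simulate_noise_free(torso$activity, torso$attenuation, g, cfg)
    set <- add_noise(set, g, cfg)
    rec <- op_osem(set$prompts_noisy[[1]], set$delayed_noisy[[1]],
                   set$scatter, attn, g, rcfg)
    counts_to_activity(rec, cfg)
  })
  stage_s["simulate_reconstruct"] <- as.numeric(Sys.time() - t1,
                                                units = "secs")
  # ROIs: organs from the label map, lesions by their labels
  lab <- torso$labels
  roi_labels <- c(lungL = 2, lungR = 3, liver = 4, spleen = 5, spine = 6)
  lesion_ids <- 10 + seq_along(config$lesions)
  names(lesion_ids) <- sprintf("lesion_%d", seq_along(config$lesions))
  all_ids <- c(roi_labels, lesion_ids)
  t2 <- Sys.time()
  feat_names <- c("peak", "mean", "median", "skewness", "cov",
                  "joint_average", "joint_entropy", "energy", "homogeneity",
                  "correlation")
  features <- array(NA_real_, c(length(all_ids), length(feat_names), 2),
                    dimnames = list(names(all_ids), feat_names,
                                    c("variant1", "variant2")))
  for (v in 1:2) for (r in seq_along(all_ids)) {
    roi <- lab == all_ids[r]
    if (!any(roi)) next
    fi <- intensity_features(imgs[[v]], roi)
    ft <- glcm_features(imgs[[v]], roi, bin_width = config$glcm_bin_width)
    features[r, , v] <- unlist(c(fi, ft))[feat_names]
  }
  feature_comparison <- lapply(stats::setNames(feat_names, feat_names),
    function(f) {
      x <- features[, f, 1]; y <- features[, f, 2]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 3 || stats::var(x[ok]) == 0) return(NULL)
      compare_features(x[ok], y[ok])
    })
  # lesion segmentation concordance
  masks <- lapply(1:2, function(v) lapply(seq_along(config$lesions),
    function(k) threshold_lesion_mask(imgs[[v]],
                                      config$lesions[[k]]$center,
                                      config$lesions[[k]]$diameter,
                                      config$threshold_fraction)))
  overlap <- lapply(seq_along(config$lesions), function(k)
    overlap_metrics(masks[[1]][[k]], masks[[2]][[k]]))
  names(overlap) <- names(lesion_ids)
  shape <- lapply(1:2, function(v) lapply(seq_along(config$lesions),
    function(k) shape_features(masks[[v]][[k]], grid)))
  shape_names <- c("volume_ml", "surface_area_cm2", "major_axis_mm",
                   "minor_axis_mm", "least_axis_mm")
  shape_ccc <- if (length(config$lesions) >= 2) {
    vapply(stats::setNames(shape_names, shape_names), function(f)
      ccc(vapply(shape[[1]], `[[`, numeric(1), f),
          vapply(shape[[2]], `[[`, numeric(1), f)), numeric(1))
  } else NULL
  stage_s["analyze"] <- as.numeric(Sys.time() - t2, units = "secs")
  manifest <- list(experiment = "concordance",
                   config = config[setdiff(names(config),
                                           c("scatter", "lesions"))],
                   lesions = config$lesions,
                   scatter = if (identical(config$scatter, "off")) "off"
                             else unclass(config$scatter),
                   geometry_preset = g$name,
                   note = paste("lesion masks use fractional-peak",
                                "auto-thresholding in place of human",
                                "analysts"),
                   stage_seconds = as.list(stage_s))
  if (!is.null(config$out)) {
    dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
    write_manifest(manifest, file.path(config$out, "manifest.json"))
  }
  list(features = features, feature_comparison = feature_comparison,
       overlap = overlap, shape = shape, shape_ccc = shape_ccc,
       manifest = manifest)
}
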