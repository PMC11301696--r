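# NEMA image-quality analysis and intensity/texture feature extraction.

roi_values <- function(img, roi) {
  if (!any(roi)) stop("empty ROI")
  img$values[roi]
}

#' Recovery coefficient
#'
#' Ratio of the observed mean activity within an ROI to the true activity,
#' quantifying partial-volume loss.
#'
#' @param img A [volume_image].
#' @param roi Logical mask on the same grid (nonempty).
#' @param true_value True activity concentration (> 0).
#' @return Scalar RC.
#' @export
recovery_coefficient <- function(img, roi, true_value) {
  if (true_value <= 0) stop("true value must be > 0")
  mean(roi_values(img, roi)) / true_value
}

#' Coefficient of variation within an ROI
#'
#' Population standard deviation over mean of the voxel values in the ROI;
#' the noise metric of the NEMA analysis.
#'
#' @inheritParams recovery_coefficient
#' @return Scalar COV.
#' @export
roi_cov <- function(img, roi) {
  v <- roi_values(img, roi)
  m <- mean(v)
  if (m == 0) stop("ROI mean is zero; COV undefined")
  sqrt(mean((v - m)^2)) / m
}

#' Voxelwise mean and STD maps across noise realizations
#'
#' @param realizations List of >= 2 [volume_image]s on the same grid.
#' @return List with `mean` and `std` [volume_image]s (population SD).
#' @export
voxelwise_mean_std <- function(realizations) {
  if (length(realizations) < 2) stop("need at least 2 realizations")
  grid <- realizations[[1]]$grid
  for (r in realizations)
    if (!identical(grid_counts(r$grid), grid_counts(grid)))
      stop("realizations must share a grid")
  n <- length(realizations)
  m <- Reduce(`+`, lapply(realizations, function(r) r$values)) / n
  ss <- Reduce(`+`, lapply(realizations, function(r) (r$values - m)^2)) / n
  list(mean = volume_image(m, grid, "reconstructed"),
       std = volume_image(sqrt(pmax(ss, 0)), grid, "reconstructed"))
}

#' Freedman-Diaconis histogram
#'
#' Bin width `2 * IQR * n^(-1/3)` with the IQR from linear-interpolation
#' quantiles; a degenerate IQR of 0 falls back to a single bin.
#'
#' @param values Numeric vector (>= 2 finite values).
#' @return List with `breaks` (bin edges) and `counts`.
#' @export
fd_histogram <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) stop("need at least 2 finite values")
  iqr <- diff(stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7))
  rng <- range(values)
  if (iqr == 0 || rng[1] == rng[2]) {
    breaks <- c(rng[1], rng[2] + max(abs(rng[2]), 1) * .Machine$double.eps +
                  (rng[2] == rng[1]))
    return(list(breaks = breaks, counts = n))
  }
  width <- 2 * iqr * n^(-1 / 3)
  nb <- max(1L, ceiling((rng[2] - rng[1]) / width))
  breaks <- rng[1] + (0:nb) * width
  counts <- tabulate(pmin(pmax(floor((values - rng[1]) / width) + 1, 1), nb),
                     nbins = nb)
  list(breaks = breaks, counts = counts)
}

#' Intensity-based features of an ROI
#'
#' Peak (mean over the voxels whose centers lie within the 1 cm^3 sphere --
#' radius 6.2035 mm -- centered at the maximum voxel's center; ties broken
#' toward the lowest linear index), mean, median, skewness (biased Fisher
#' moment coefficient `m3 / m2^1.5`, defined as 0 for constant input) and
#' coefficient of variation.
#'
#' @param img A [volume_image].
#' @param roi Logical mask (nonempty).
#' @return Named list: `peak`, `mean`, `median`, `skewness`, `cov`.
#' @export
intensity_features <- function(img, roi) {
  v <- roi_values(img, roi)
  grid <- img$grid
  idx_roi <- which(roi)
  max_idx <- idx_roi[which.max(img$values[idx_roi])]
  ctr <- arrayInd(max_idx, grid_counts(grid))
  pc <- grid$origin + (as.numeric(ctr) - 1) * grid_sizes(grid)
  r_peak <- (3 * 1000 / (4 * pi))^(1 / 3)  # 1 cm^3 sphere radius in mm
  # voxel count of a nominal peak sphere, for the small-ROI warning
  if (length(v) * voxel_volume_ml(grid) < 1)
    warning("ROI smaller than the 1 cm^3 peak sphere; peak uses available voxels")
  rad_vox <- ceiling(r_peak / grid_sizes(grid))
  lo <- pmax(as.numeric(ctr) - rad_vox, 1)
  hi <- pmin(as.numeric(ctr) + rad_vox, grid_counts(grid))
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  px <- grid_axis_centers(grid, 1)[ix]
  py <- grid_axis_centers(grid, 2)[iy]
  pz <- grid_axis_centers(grid, 3)[iz]
  dist2 <- outer(outer((px - pc[1])^2, (py - pc[2])^2, "+"),
                 (pz - pc[3])^2, "+")
  nb <- img$values[ix, iy, iz, drop = FALSE]
  peak <- mean(nb[dist2 <= r_peak^2])
  m <- mean(v)
  m2 <- mean((v - m)^2); m3 <- mean((v - m)^3)
  skew <- if (m2 == 0) 0 else m3 / m2^1.5
  list(peak = peak, mean = m, median = stats::median(v), skewness = skew,
       cov = if (m == 0) NA_real_ else sqrt(m2) / m)
}

# Symmetric distance-1 GLCM counts for one in-plane direction, pooled over
# transaxial slices; counts only voxel pairs that are both inside the ROI.
glcm_counts_direction <- function(levels, roi, offset) {
  nlev <- max(levels[roi])
  dims <- dim(levels)
  counts <- matrix(0, nlev, nlev)
  ox <- offset[1]; oy <- offset[2]
  x1 <- max(1, 1 - ox):min(dims[1], dims[1] - ox)
  y1 <- max(1, 1 - oy):min(dims[2], dims[2] - oy)
  if (!length(x1) || !length(y1)) return(counts)
  for (z in seq_len(dims[3])) {
    a <- levels[x1, y1, z, drop = FALSE]
    b <- levels[x1 + ox, y1 + oy, z, drop = FALSE]
    ok <- roi[x1, y1, z, drop = FALSE] & roi[x1 + ox, y1 + oy, z, drop = FALSE]
    if (!any(ok)) next
    tab <- table(factor(a[ok], levels = seq_len(nlev)),
                 factor(b[ok], levels = seq_len(nlev)))
    counts <- counts + tab + t(tab)
  }
  counts
}

glcm_features_one <- function(pmat) {
  nlev <- nrow(pmat)
  i <- row(pmat); j <- col(pmat)
  mu_i <- sum(i * pmat); mu_j <- sum(j * pmat)
  sd_i <- sqrt(sum((i - mu_i)^2 * pmat)); sd_j <- sqrt(sum((j - mu_j)^2 * pmat))
  ent <- -sum(ifelse(pmat > 0, pmat * log2(pmat), 0))
  corr <- if (sd_i == 0 || sd_j == 0) NA_real_ else
    sum((i - mu_i) * (j - mu_j) * pmat) / (sd_i * sd_j)
  list(joint_average = mu_i,
       joint_entropy = ent,
       energy = sum(pmat^2),
       homogeneity = sum(pmat / (1 + abs(i - j))),
       correlation = corr)
}

#' Grey-level co-occurrence (GLCM) texture features
#'
#' Voxels are discretized to levels `floor(v / bin_width) + 1` (absolute
#' lower edge at 0, since the bin width is an absolute intensity). Per
#' transaxial slice, symmetric distance-1 co-occurrence counts are built for
#' the four in-plane directions (0, 45, 90, 135 degrees) over voxel pairs
#' that are both inside the ROI; counts are pooled over slices per
#' direction, each direction's matrix is normalized to sum 1, and the five
#' features are averaged over the four directions.
#'
#' @param img A [volume_image].
#' @param roi Logical mask (nonempty).
#' @param bin_width Discretization bin width in the image's intensity units
#'   (default 100, intended for images in kBq/ml).
#' @return Named list: `joint_average`, `joint_entropy`, `energy`,
#'   `homogeneity`, `correlation` (direction averages).
#' @export
glcm_features <- function(img, roi, bin_width = 100) {
  if (!any(roi)) stop("empty ROI")
  levels <- floor(pmax(img$values, 0) / bin_width) + 1L
  dim(levels) <- dim(img$values)
  offsets <- list(c(1L, 0L), c(1L, 1L), c(0L, 1L), c(-1L, 1L))
  feats <- list()
  for (o in offsets) {
    counts <- glcm_counts_direction(levels, roi, o)
    tot <- sum(counts)
    if (tot == 0) {
      warning("no in-ROI voxel pairs for direction (", o[1], ",", o[2],
              "); direction skipped")
      next
    }
    feats[[length(feats) + 1]] <- glcm_features_one(counts / tot)
  }
  if (!length(feats)) stop("no GLCM direction had any in-ROI voxel pairs")
  nm <- names(feats[[1]])
  out <- lapply(nm, function(f)
    mean(vapply(feats, function(x) x[[f]], numeric(1)), na.rm = TRUE))
  names(out) <- nm
  out
}

#' Compare paired feature lists by linear regression and Pearson correlation
#'
#' Ordinary least squares of `y` on `x` with t-based 95% confidence
#' intervals on slope and intercept, plus the Pearson product-moment
#' correlation.
#'
#' @param x,y Paired numeric vectors (n >= 3, nonzero variance in x).
#' @return List with `slope`, `intercept`, `slope_ci`, `intercept_ci`
#'   (95% CIs) and `pearson_r`.
#' @export
compare_features <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need >= 3 paired values")
  if (stats::var(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  # zero-width CIs on exact fits trigger a harmless precision warning
  ci <- suppressWarnings(stats::confint(fit, level = 0.95))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       slope_ci = unname(ci[2, ]),
       intercept_ci = unname(ci[1, ]),
       pearson_r = stats::cor(x, y))
}

# Logical sphere mask from center (mm) and diameter (mm): voxel centers
# within the radius.
sphere_mask <- function(grid, center, diameter) {
  xs <- grid_axis_centers(grid, 1); ys <- grid_axis_centers(grid, 2)
  zs <- grid_axis_centers(grid, 3)
  d2 <- outer(outer((xs - center[1])^2, (ys - center[2])^2, "+"),
              (zs - center[3])^2, "+")
  d2 <= (diameter / 2)^2
}

#' NEMA analysis regions of interest
#'
#' Six sphere-shaped ROIs of the same size and position as the inserted
#' spheres, plus a background annulus about the phantom axis replicated on
#' the sphere plane's slice and its 2 neighbors on each side (5 slices).
#' The default radii (inner 80 mm, outer 110 mm) start outside the largest
#' sphere's radial reach (57.2 + 18.5 mm), and the annulus is clipped to the
#' body interior eroded by `body_margin_mm` so it contains only warm
#' background. An error is raised if the annulus intersects any sphere ROI.
#'
#' @param grid A [voxel_grid].
#' @param spec The phantom spec returned by [make_nema_iq()].
#' @param annulus_inner_mm,annulus_outer_mm Background annulus radii.
#' @param body_margin_mm Margin kept to the body wall.
#' @return List with `spheres` (list of 6 masks, named by diameter) and
#'   `background`.
#' @export
nema_rois <- function(grid, spec, annulus_inner_mm = 80,
                      annulus_outer_mm = 110, body_margin_mm = 10) {
  spheres <- lapply(seq_along(spec$sphere_diameters_mm), function(k) {
    m <- sphere_mask(grid, spec$sphere_centers[k, ],
                     spec$sphere_diameters_mm[k])
    if (!any(m)) {
      # grid coarser than the sphere: degenerate to the nearest voxel so the
      # ROI keeps its position
      ctr <- spec$sphere_centers[k, ]
      idx <- pmin(pmax(round((ctr - grid$origin) / grid_sizes(grid)) + 1, 1),
                  grid_counts(grid))
      m[idx[1], idx[2], idx[3]] <- TRUE
    }
    m
  })
  names(spheres) <- sprintf("sphere_%dmm", spec$sphere_diameters_mm)
  zs <- grid_axis_centers(grid, 3)
  kz <- which.min(abs(zs - spec$sphere_plane_z))
  zset <- unique(pmin(pmax(kz + (-2:2), 1), grid$nz))
  xs <- grid_axis_centers(grid, 1); ys <- grid_axis_centers(grid, 2)
  r2 <- outer(xs^2, ys^2, "+")
  ann2d <- r2 >= annulus_inner_mm^2 & r2 <= annulus_outer_mm^2
  if (!is.null(spec$body_R_mm)) {
    eroded <- shape("dcylinder", c(0, 0, spec$sphere_plane_z),
                    c(spec$body_R_mm - body_margin_mm,
                      spec$body_rc_mm - body_margin_mm, spec$body_len_mm))
    px <- rep(xs, times = length(ys)); py <- rep(ys, each = length(xs))
    inside <- matrix(shape_inside(eroded, px, py,
                                  rep(spec$sphere_plane_z, length(px))),
                     length(xs), length(ys))
    ann2d <- ann2d & inside
  }
  bg <- array(FALSE, grid_counts(grid))
  for (z in zset) bg[, , z] <- ann2d
  for (k in seq_along(spheres))
    if (any(bg & spheres[[k]]))
      stop("background annulus intersects sphere ROI ", names(spheres)[k])
  list(spheres = spheres, background = bg)
}
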