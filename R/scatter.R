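# Single-scatter estimation in 2D mode plus axial expansion by inverse
# single-slice rebinning.
#
# The 2D single-scatter model follows the classic model-based construction:
# scatter points are placed deterministically on a coarse sub-grid of the
# attenuating volume; for each LOR and scatter point the contribution is the
# product of the emission line integrals from each detector to the point,
# attenuation along both legs (511 keV attenuation used for both legs -- a
# documented simplification), the Klein-Nishina differential cross-section
# at the scattering angle, inverse-square solid-angle factors, the local
# attenuation coefficient as electron-density surrogate, and an
# energy-window acceptance indicator on the scattered-photon energy.
# Absolute scaling is deferred to scale_scatter().

#' Scatter estimation configuration
#'
#' @param n_scatter_points Target number of scatter points per slice.
#' @param energy_window_keV Acquisition energy window `(low, high)` in keV.
#' @param scatter_fraction_target Fraction in (0, 1) that
#'   [scale_scatter()] should enforce (scatter / prompts), or `"absolute"`
#'   to leave the estimate unscaled.
#' @param smoothing_fwhm_bins FWHM (radial bins) of the Gaussian applied to
#'   the raw 2D estimate.
#' @return An object of class `scatter_config`.
#' @export
scatter_config <- function(n_scatter_points = 500,
                           energy_window_keV = c(435, 585),
                           scatter_fraction_target = 0.30,
                           smoothing_fwhm_bins = 4) {
  if (n_scatter_points < 1) stop("n_scatter_points must be >= 1")
  ew <- energy_window_keV
  if (length(ew) != 2 || ew[1] <= 0 || ew[2] <= ew[1])
    stop("energy window must satisfy 0 < low < high")
  if (is.numeric(scatter_fraction_target) &&
      (scatter_fraction_target <= 0 || scatter_fraction_target >= 1))
    stop("fractional scatter_fraction_target must be in (0, 1)")
  if (smoothing_fwhm_bins < 0) stop("smoothing_fwhm_bins must be >= 0")
  structure(list(n_scatter_points = n_scatter_points,
                 energy_window_keV = ew,
                 scatter_fraction_target = scatter_fraction_target,
                 smoothing_fwhm_bins = smoothing_fwhm_bins),
            class = "scatter_config")
}

# Bilinear interpolation of a 2D field at physical points; zero outside.
bilinear_at <- function(field, grid, px, py) {
  fx <- (px - grid$origin[1]) / grid$dx
  fy <- (py - grid$origin[2]) / grid$dy
  i0 <- floor(fx); j0 <- floor(fy)
  a <- fx - i0; b <- fy - j0
  nx <- grid$nx; ny <- grid$ny
  val <- numeric(length(px))
  for (dxi in 0:1) for (dyi in 0:1) {
    ii <- i0 + dxi + 1L; jj <- j0 + dyi + 1L
    w <- (if (dxi) a else 1 - a) * (if (dyi) b else 1 - b)
    ok <- ii >= 1L & ii <= nx & jj >= 1L & jj <= ny & w > 0
    if (any(ok)) val[ok] <- val[ok] + w[ok] * field[ii[ok] + (jj[ok] - 1L) * nx]
  }
  val
}

#' 2D single-scatter estimate for one image slice
#'
#' @param activity,mu [volume_image]s sharing a grid (activity Bq/ml,
#'   attenuation 1/cm).
#' @param g A [scanner_geometry].
#' @param cfg A [scatter_config].
#' @param slice_index Image slice (1-based z index).
#' @param n_ray_samples Samples per detector leg integral.
#' @return A `(n_projections, n_views)` matrix of non-negative scatter
#'   values (arbitrary scale; see [scale_scatter()]).
#' @export
estimate_scatter_2d <- function(activity, mu, g, cfg = scatter_config(),
                                slice_index, n_ray_samples = 24) {
  if (!identical(grid_counts(activity$grid), grid_counts(mu$grid)))
    stop("activity and mu must share a grid")
  grid <- activity$grid
  if (slice_index < 1 || slice_index > grid$nz)
    stop("slice index out of range")
  a2 <- activity$values[, , slice_index]
  m2 <- mu$values[, , slice_index]
  nproj <- g$n_projections; nview <- g$n_views
  out <- matrix(0, nproj, nview)
  cand <- which(m2 > 0.005)
  if (!length(cand) || sum(a2) == 0) return(out)
  step <- max(1L, floor(length(cand) / cfg$n_scatter_points))
  pts <- cand[seq(1L, length(cand), by = step)]
  xs <- grid_axis_centers(grid, 1); ys <- grid_axis_centers(grid, 2)
  pij <- arrayInd(pts, dim(m2))
  Pxy <- cbind(xs[pij[, 1]], ys[pij[, 2]])
  muP <- m2[pts]
  # discretized detector ring
  D <- max(48L, 2L * nview)
  th <- (seq_len(D) - 1) * 2 * pi / D
  det <- g$ring_radius_mm * cbind(cos(th), sin(th))
  # LOR endpoints -> nearest ring detector
  soff <- radial_offsets(g); phis <- view_angles(g)
  smat <- matrix(soff, nproj, nview)
  pmat <- matrix(phis, nproj, nview, byrow = TRUE)
  te <- sqrt(pmax(g$ring_radius_mm^2 - smat^2, 0))
  e1x <- smat * cos(pmat) - te * sin(pmat); e1y <- smat * sin(pmat) + te * cos(pmat)
  e2x <- smat * cos(pmat) + te * sin(pmat); e2y <- smat * sin(pmat) - te * cos(pmat)
  toidx <- function(x, y) {
    a <- atan2(y, x); a[a < 0] <- a[a < 0] + 2 * pi
    (round(a / (2 * pi / D)) %% D) + 1L
  }
  d1 <- toidx(e1x, e1y); d2 <- toidx(e2x, e2y)
  fr <- (seq_len(n_ray_samples) - 0.5) / n_ray_samples
  low <- cfg$energy_window_keV[1]; high <- cfg$energy_window_keV[2]
  nP <- nrow(Pxy); K <- n_ray_samples
  # leg vectors P -> detector for every (detector, scatter point)
  DVX <- outer(det[, 1], Pxy[, 1], "-")    # D x nP
  DVY <- outer(det[, 2], Pxy[, 2], "-")
  LEN <- sqrt(DVX^2 + DVY^2)
  UX <- DVX / LEN; UY <- DVY / LEN
  # sample all leg integrals in one interpolation call per field;
  # outer(DVX, fr) has dims (D, nP, K), rearranged to (D, K, nP)
  tmp <- aperm(outer(DVX, fr), c(1, 3, 2))
  SX <- array(rep(Pxy[, 1], each = D * K), c(D, K, nP)) + tmp
  tmp <- aperm(outer(DVY, fr), c(1, 3, 2))
  SY <- array(rep(Pxy[, 2], each = D * K), c(D, K, nP)) + tmp
  leg_integral <- function(field) {
    v <- array(bilinear_at(field, grid, as.vector(SX), as.vector(SY)),
               c(D, K, nP))
    colSums(aperm(v, c(2, 1, 3))) * LEN / K   # sum over samples -> D x nP
  }
  Ia <- leg_integral(a2)
  Im <- leg_integral(m2)
  # scattering angle per (LOR, point): the photon reaching detector 2
  # arrives at the scatter point travelling along detector1 -> point, so
  # cos(theta) = -u1 . u2
  cosq <- -(UX[d1, , drop = FALSE] * UX[d2, , drop = FALSE] +
              UY[d1, , drop = FALSE] * UY[d2, , drop = FALSE])
  epsE <- 1 / (2 - cosq)                  # scattered energy fraction E'/511
  acc <- (511 * epsE >= low) & (511 * epsE <= high)
  kn <- epsE^2 * (epsE + 1 / epsE - (1 - cosq^2))
  attf <- exp(-(Im[d1, , drop = FALSE] + Im[d2, , drop = FALSE]) / 10)
  emis <- Ia[d1, , drop = FALSE] + Ia[d2, , drop = FALSE]
  geomf <- 1 / (LEN[d1, , drop = FALSE]^2 * LEN[d2, , drop = FALSE]^2)
  contrib <- (kn * acc * attf * emis * geomf) %*% muP
  out <- out + matrix(contrib, nproj, nview)
  if (cfg$smoothing_fwhm_bins > 0) {
    sig <- cfg$smoothing_fwhm_bins / (2 * sqrt(2 * log(2)))
    out <- apply(out, 2, gaussian_smooth_1d, sigma = sig)
  }
  out[out < 0] <- 0
  out
}

#' Expand a stack of 2D scatter estimates to 3D by inverse SSRB
#'
#' Each of the geometry's axial planes receives the 2D estimate linearly
#' interpolated between the two nearest image-slice axial positions
#' (clamped at the ends).
#'
#' @param slices Array `(n_projections, n_views, n_slices)` -- one 2D
#'   sinogram per image slice -- or a list of matrices.
#' @param g A [scanner_geometry].
#' @param grid The [voxel_grid] the slices belong to (provides axial
#'   positions).
#' @return A non-TOF [sinogram].
#' @export
inverse_ssrb <- function(slices, g, grid) {
  if (is.list(slices)) slices <- simplify2array(slices)
  if (length(dim(slices)) == 2) dim(slices) <- c(dim(slices), 1L)
  if (dim(slices)[3] == 0 || length(slices) == 0) stop("empty slice stack")
  if (dim(slices)[3] != grid$nz)
    stop("need one 2D sinogram per image slice")
  P <- build_axial_interp(g, grid)
  nlor <- g$n_projections * g$n_views
  S2 <- slices; dim(S2) <- c(nlor, grid$nz)
  out <- as.matrix(S2 %*% Matrix::t(P))
  sinogram(array(out, c(g$n_projections, g$n_views, g$n_planes)), g,
           tof = FALSE)
}

#' Scale a scatter sinogram to a target scatter fraction
#'
#' With a fractional target `f`, the scatter sinogram is globally scaled so
#' that `sum(scatter) / (sum(scatter) + sum(trues)) = f` exactly; with
#' `"absolute"` the estimate is returned unscaled.
#'
#' @param scatter,trues [sinogram]s of matching geometry.
#' @param cfg A [scatter_config].
#' @return The scaled scatter [sinogram].
#' @export
scale_scatter <- function(scatter, trues, cfg = scatter_config()) {
  tgt <- cfg$scatter_fraction_target
  if (identical(tgt, "absolute")) return(scatter)
  if (!is.numeric(tgt) || tgt <= 0 || tgt >= 1)
    stop("fractional scatter target must be in (0, 1)")
  ss <- sum(scatter$values); st <- sum(trues$values)
  if (ss == 0) {
    warning("scatter estimate is identically zero; cannot scale")
    return(scatter)
  }
  alpha <- tgt * st / ((1 - tgt) * ss)
  sinogram(scatter$values * alpha, scatter$geometry, tof = scatter$tof)
}
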