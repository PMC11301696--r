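# Small geometries and phantoms shared across tests. Everything is built in
# code at test time; nothing is read from disk.

# A desk-scale scanner: 48 radial bins x 24 views x 4 direct planes over a
# 128 mm transaxial / 16 mm axial FOV, matched to a 32x32x4 grid of 4 mm
# voxels (plane centers coincide with slice centers).
tiny_geometry <- function(n_tof_bins = 5) {
  scanner_geometry("tiny", ring_radius_mm = 200, n_projections = 48,
                   n_views = 24, n_planes = 4, span = 1,
                   n_tof_bins = n_tof_bins, tof_bin_width_ps = 200,
                   timing_resolution_ps = 400, fov_transaxial_mm = 128,
                   fov_axial_mm = 16)
}

tiny_grid <- function() voxel_grid(32, 32, 4, 4, 4, 4)

# Warm cylinder with one hot sphere: a well-conditioned smooth test object.
tiny_phantom <- function(grid = tiny_grid()) {
  spec <- phantom_spec(list(
    shape("cylinder", c(0, 0, 0), c(50, 1000), activity = 100,
          attenuation = 0.096),
    shape("sphere", c(15, 5, 0), 20, activity = 400, attenuation = 0.096)))
  list(activity = rasterize(spec, grid, 3, "activity"),
       attenuation = rasterize(spec, grid, 3, "attenuation"))
}

zero_sinogram <- function(g, tof = FALSE) {
  d <- c(g$n_projections, g$n_views, g$n_planes)
  if (tof) d <- c(d, g$n_tof_bins)
  sinogram(array(0, d), g, tof = tof)
}

random_volume <- function(grid, seed = 1) {
  set.seed(seed)
  volume_image(array(stats::runif(prod(c(grid$nx, grid$ny, grid$nz))),
                     c(grid$nx, grid$ny, grid$nz)), grid, "activity")
}

# FWHM of a 1D profile by linear interpolation at half maximum.
measure_fwhm <- function(prof, spacing) {
  pk <- which.max(prof)
  h <- prof[pk] / 2
  left <- max(which(prof[seq_len(pk)] <= h))
  right <- pk - 1 + min(which(prof[pk:length(prof)] <= h))
  xl <- left + (h - prof[left]) / (prof[left + 1] - prof[left])
  xr <- right - 1 + (prof[right - 1] - h) / (prof[right - 1] - prof[right])
  (xr - xl) * spacing
}

# Logical sphere mask for ad-hoc grids.
ball_mask <- function(grid, center, diameter) {
  xs <- grid$origin[1] + (seq_len(grid$nx) - 1) * grid$dx
  ys <- grid$origin[2] + (seq_len(grid$ny) - 1) * grid$dy
  zs <- grid$origin[3] + (seq_len(grid$nz) - 1) * grid$dz
  d2 <- outer(outer((xs - center[1])^2, (ys - center[2])^2, "+"),
              (zs - center[3])^2, "+")
  d2 <= (diameter / 2)^2
}
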