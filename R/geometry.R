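# Scanner and image-grid descriptions.
#
# The pipeline operates directly in sinogram coordinates (radial offset,
# azimuthal view, axial plane, optional TOF bin); lines of response are
# parameterized by those coordinates rather than by crystal pairs, so a
# geometry is fully described by its sinogram dimensioning plus the physical
# field of view and bore radius.

#' Voxel grid description
#'
#' A regular 3D voxel grid: counts per axis, edge lengths in mm, and the
#' physical coordinate (mm) of the center of voxel `(0, 0, 0)` (0-based
#' indices). By default the grid is centered on the scanner axis, i.e. the
#' physical extent `count * edge` is symmetric about the origin.
#'
#' @param nx,ny,nz Voxel counts per axis (integers >= 1).
#' @param dx,dy,dz Voxel edge lengths in mm (> 0).
#' @param origin Physical coordinate (mm) of the center of the first voxel.
#'   `NULL` (default) centers the grid on the origin.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(nx, ny, nz, dx, dy, dz, origin = NULL) {
  counts <- c(nx, ny, nz)
  sizes <- c(dx, dy, dz)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("voxel counts must be integers >= 1")
  if (any(sizes <= 0)) stop("voxel edge lengths must be > 0")
  if (is.null(origin)) origin <- -(counts - 1) / 2 * sizes
  if (length(origin) != 3) stop("origin must have 3 components")
  structure(list(nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
                 dx = dx, dy = dy, dz = dz, origin = as.numeric(origin)),
            class = "voxel_grid")
}

#' @export
format.voxel_grid <- function(x, ...) {
  sprintf("voxel_grid %dx%dx%d @ %.4gx%.4gx%.4g mm", x$nx, x$ny, x$nz,
          x$dx, x$dy, x$dz)
}

#' @export
print.voxel_grid <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

grid_counts <- function(grid) c(grid$nx, grid$ny, grid$nz)
grid_sizes <- function(grid) c(grid$dx, grid$dy, grid$dz)

# Physical center coordinates of voxels along one axis (1 = x, 2 = y, 3 = z).
grid_axis_centers <- function(grid, axis) {
  n <- grid_counts(grid)[axis]
  grid$origin[axis] + (seq_len(n) - 1) * grid_sizes(grid)[axis]
}

# Voxel volume in ml (mm^3 -> ml is /1000).
voxel_volume_ml <- function(grid) grid$dx * grid$dy * grid$dz / 1000

#' Scanner geometry description
#'
#' Describes a cylindrical PET scanner at the sinogram level: the number of
#' radial bins (`n_projections`), azimuthal views after angular mashing
#' (`n_views`), axial sinogram planes after span compression (`n_planes`),
#' and TOF bins (`n_tof_bins`, odd so the bins are symmetric around zero time
#' difference), plus the physical transaxial/axial field of view and the bore
#' (detector ring) radius. The `n_planes` axial planes are laid out uniformly
#' over the axial field of view.
#'
#' @param name Preset label.
#' @param ring_radius_mm Detector ring radius (mm).
#' @param n_projections Number of radial bins.
#' @param n_views Number of azimuthal views (mashed).
#' @param n_planes Number of axial sinogram planes (span-compressed).
#' @param span Axial compression span (metadata; planes are laid out
#'   uniformly over the axial FOV).
#' @param n_tof_bins Number of TOF bins (odd).
#' @param tof_bin_width_ps TOF bin width in picoseconds.
#' @param timing_resolution_ps Coincidence timing resolution (FWHM, ps).
#' @param fov_transaxial_mm,fov_axial_mm Physical field of view (mm).
#' @return An object of class `scanner_geometry`.
#' @export
scanner_geometry <- function(name, ring_radius_mm, n_projections, n_views,
                             n_planes, span, n_tof_bins,
                             tof_bin_width_ps, timing_resolution_ps,
                             fov_transaxial_mm, fov_axial_mm) {
  g <- structure(list(name = name, ring_radius_mm = ring_radius_mm,
                      n_projections = as.integer(n_projections),
                      n_views = as.integer(n_views),
                      n_planes = as.integer(n_planes), span = as.integer(span),
                      n_tof_bins = as.integer(n_tof_bins),
                      tof_bin_width_ps = tof_bin_width_ps,
                      timing_resolution_ps = timing_resolution_ps,
                      fov_transaxial_mm = fov_transaxial_mm,
                      fov_axial_mm = fov_axial_mm),
                 class = "scanner_geometry")
  bad <- validate_geometry(g)
  if (length(bad)) stop("invalid scanner geometry: ",
                        paste(bad, collapse = "; "))
  g
}

#' @export
format.scanner_geometry <- function(x, ...) {
  sprintf("scanner_geometry '%s': %d proj x %d views x %d planes x %d TOF",
          x$name, x$n_projections, x$n_views, x$n_planes, x$n_tof_bins)
}

#' @export
print.scanner_geometry <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Vision-600 geometry preset
#'
#' The reference whole-body TOF PET/CT geometry used throughout the package:
#' sinograms of 520 radial bins x 50 mashed views x 815 span-19 axial planes
#' x 33 TOF bins, a 726.0 x 726.0 x 261.714 mm field of view, and the matched
#' default image grid of 440 x 440 x 159 voxels of 1.65 x 1.65 x 1.646 mm.
#'
#' TOF bin width and timing resolution are not part of the sinogram
#' dimensioning; the defaults here (80 ps bins, 210 ps FWHM timing
#' resolution) are nominal values and are freely overridable by constructing
#' a [scanner_geometry()] directly.
#'
#' @return A list with elements `geometry` ([scanner_geometry]) and `grid`
#'   ([voxel_grid]).
#' @examples
#' v <- make_vision600()
#' v$geometry$n_planes       # 815
#' v$grid$nx * v$grid$dx     # 726 mm transaxial FOV
#' @export
make_vision600 <- function() {
  grid <- voxel_grid(440, 440, 159, 1.65, 1.65, 1.646)
  g <- scanner_geometry(name = "vision600", ring_radius_mm = 410,
                        n_projections = 520, n_views = 50, n_planes = 815,
                        span = 19, n_tof_bins = 33, tof_bin_width_ps = 80,
                        timing_resolution_ps = 210,
                        fov_transaxial_mm = 726.0,
                        fov_axial_mm = 261.714)
  list(geometry = g, grid = grid)
}

#' Deterministically scaled geometry for desk-scale runs
#'
#' Scales all sinogram and grid counts of the Vision-600 preset by `scale`
#' (rounded, minimum 1, TOF bin count forced odd) while preserving the
#' physical field of view: voxel sizes and radial spacing are recomputed so
#' that `count * size` is unchanged. `scale = 1` reproduces
#' [make_vision600()] exactly.
#'
#' @param scale Positive fraction in (0, 1].
#' @return A list with elements `geometry` and `grid`.
#' @export
make_scaled_geometry <- function(scale) {
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0 || scale > 1)
    stop("scale must be a single number in (0, 1]")
  ref <- make_vision600()
  g0 <- ref$geometry; gr0 <- ref$grid
  sc <- function(n) max(1L, as.integer(round(n * scale)))
  ntof <- sc(g0$n_tof_bins)
  if (ntof %% 2L == 0L) ntof <- ntof + 1L
  nx <- sc(gr0$nx); ny <- sc(gr0$ny); nz <- sc(gr0$nz)
  grid <- voxel_grid(nx, ny, nz,
                     g0$fov_transaxial_mm / nx, g0$fov_transaxial_mm / ny,
                     g0$fov_axial_mm / nz)
  g <- scanner_geometry(name = if (scale == 1) "vision600"
                               else sprintf("vision600:%g", scale),
                        ring_radius_mm = g0$ring_radius_mm,
                        n_projections = sc(g0$n_projections),
                        n_views = sc(g0$n_views),
                        n_planes = sc(g0$n_planes),
                        span = g0$span, n_tof_bins = ntof,
                        tof_bin_width_ps = g0$tof_bin_width_ps,
                        timing_resolution_ps = g0$timing_resolution_ps,
                        fov_transaxial_mm = g0$fov_transaxial_mm,
                        fov_axial_mm = g0$fov_axial_mm)
  list(geometry = g, grid = grid)
}

#' Validate a scanner geometry (and optionally a grid against it)
#'
#' Checks the type invariants and, when a grid is supplied, that the grid
#' fits inside the scanner bore (transaxial extent per axis no larger than
#' the bore diameter). Violations are returned as messages, not raised.
#'
#' @param g A [scanner_geometry].
#' @param grid Optional [voxel_grid] to check against the bore.
#' @return Character vector of violation messages (empty if valid).
#' @export
validate_geometry <- function(g, grid = NULL) {
  v <- character()
  counts <- c(n_projections = g$n_projections, n_views = g$n_views,
              n_planes = g$n_planes, n_tof_bins = g$n_tof_bins)
  for (nm in names(counts))
    if (is.na(counts[[nm]]) || counts[[nm]] < 1)
      v <- c(v, sprintf("%s must be >= 1", nm))
  if (!is.na(g$n_tof_bins) && g$n_tof_bins %% 2L == 0L)
    v <- c(v, "n_tof_bins must be odd (TOF bins symmetric around zero)")
  if (g$fov_transaxial_mm >= 2 * g$ring_radius_mm)
    v <- c(v, "fov_transaxial_mm must be < 2 * ring_radius_mm")
  if (g$fov_transaxial_mm <= 0 || g$fov_axial_mm <= 0)
    v <- c(v, "fields of view must be > 0")
  if (g$tof_bin_width_ps <= 0 || g$timing_resolution_ps <= 0)
    v <- c(v, "TOF bin width and timing resolution must be > 0")
  if (!is.null(grid)) {
    if (grid$nx * grid$dx > 2 * g$ring_radius_mm ||
        grid$ny * grid$dy > 2 * g$ring_radius_mm)
      v <- c(v, "grid transaxial extent exceeds the scanner bore")
  }
  v
}

# Axial positions (mm) of the sinogram plane centers: uniform layout over the
# axial FOV, symmetric about z = 0.
plane_z_positions <- function(g) {
  dzp <- g$fov_axial_mm / g$n_planes
  -g$fov_axial_mm / 2 + (seq_len(g$n_planes) - 0.5) * dzp
}

# Radial bin center offsets (mm): spacing fov_transaxial / n_projections,
# symmetric about 0.
radial_offsets <- function(g) {
  ds <- g$fov_transaxial_mm / g$n_projections
  (seq_len(g$n_projections) - (g$n_projections + 1) / 2) * ds
}

# Azimuthal view angles, uniform over [0, pi).
view_angles <- function(g) (seq_len(g$n_views) - 1) * pi / g$n_views

#' Write / read a geometry preset as key-value text
#'
#' Flat `key = value` text serialization for [scanner_geometry] /
#' [voxel_grid] pairs; the preset name `vision600` is reserved for the
#' built-in preset.
#'
#' @param geom List with `geometry` and `grid` (as returned by the preset
#'   constructors).
#' @param path File path.
#' @return `read_geometry` returns a list with `geometry` and `grid`.
#' @export
write_geometry <- function(geom, path) {
  g <- geom$geometry; grid <- geom$grid
  num <- function(x) format(x, digits = 15)
  lines <- c(
    paste0("name = ", g$name),
    sprintf("ring_radius_mm = %s", num(g$ring_radius_mm)),
    sprintf("n_projections = %d", g$n_projections),
    sprintf("n_views = %d", g$n_views),
    sprintf("n_planes = %d", g$n_planes),
    sprintf("span = %d", g$span),
    sprintf("n_tof_bins = %d", g$n_tof_bins),
    sprintf("tof_bin_width_ps = %s", num(g$tof_bin_width_ps)),
    sprintf("timing_resolution_ps = %s", num(g$timing_resolution_ps)),
    sprintf("fov_transaxial_mm = %s", num(g$fov_transaxial_mm)),
    sprintf("fov_axial_mm = %s", num(g$fov_axial_mm)),
    sprintf("grid_counts = %d %d %d", grid$nx, grid$ny, grid$nz),
    sprintf("grid_sizes_mm = %s %s %s", num(grid$dx), num(grid$dy),
            num(grid$dz)),
    sprintf("grid_origin_mm = %s %s %s", num(grid$origin[1]),
            num(grid$origin[2]), num(grid$origin[3])))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  kv <- read_keyvalue(path)
  counts <- as.numeric(strsplit(kv$grid_counts, "\\s+")[[1]])
  sizes <- as.numeric(strsplit(kv$grid_sizes_mm, "\\s+")[[1]])
  org <- as.numeric(strsplit(kv$grid_origin_mm, "\\s+")[[1]])
  grid <- voxel_grid(counts[1], counts[2], counts[3],
                     sizes[1], sizes[2], sizes[3], origin = org)
  g <- scanner_geometry(name = kv$name,
                        ring_radius_mm = as.numeric(kv$ring_radius_mm),
                        n_projections = as.numeric(kv$n_projections),
                        n_views = as.numeric(kv$n_views),
                        n_planes = as.numeric(kv$n_planes),
                        span = as.numeric(kv$span),
                        n_tof_bins = as.numeric(kv$n_tof_bins),
                        tof_bin_width_ps = as.numeric(kv$tof_bin_width_ps),
                        timing_resolution_ps =
                          as.numeric(kv$timing_resolution_ps),
                        fov_transaxial_mm = as.numeric(kv$fov_transaxial_mm),
                        fov_axial_mm = as.numeric(kv$fov_axial_mm))
  list(geometry = g, grid = grid)
}

# Parse "key = value" lines into a named list of strings.
read_keyvalue <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  out <- lapply(parts, function(p) trimws(p[2]))
  names(out) <- vapply(parts, function(p) trimws(p[1]), character(1))
  out
}

#' Resolve a geometry preset string
#'
#' Accepts `"vision600"` or `"vision600:<scale>"` (e.g. `"vision600:0.25"`),
#' or a path to a key-value preset file written by [write_geometry()].
#'
#' @param preset Preset string or file path.
#' @return A list with `geometry` and `grid`.
#' @export
resolve_geometry <- function(preset) {
  if (file.exists(preset)) return(read_geometry(preset))
  if (identical(preset, "vision600")) return(make_vision600())
  if (startsWith(preset, "vision600:")) {
    sc <- as.numeric(sub("^vision600:", "", preset))
    if (is.na(sc)) stop("cannot parse geometry scale in preset: ", preset)
    return(make_scaled_geometry(sc))
  }
  stop("unknown geometry preset: ", preset)
}
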