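# Voxelized activity/attenuation phantom generation.

#' 3D scalar field on a voxel grid
#'
#' @param values 3D numeric array matching the grid counts.
#' @param grid A [voxel_grid].
#' @param quantity One of `"activity"` (Bq/ml), `"attenuation"` (1/cm) or
#'   `"reconstructed"`.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(values, grid,
                         quantity = c("activity", "attenuation",
                                      "reconstructed")) {
  quantity <- match.arg(quantity)
  if (!identical(dim(values), as.integer(grid_counts(grid))))
    stop("values shape does not match grid counts")
  if (any(!is.finite(values))) stop("values must be finite")
  if (quantity %in% c("activity", "attenuation") && any(values < 0))
    stop(quantity, " values must be >= 0")
  structure(list(values = values, grid = grid, quantity = quantity),
            class = "volume_image")
}

#' @export
format.volume_image <- function(x, ...) {
  sprintf("volume_image [%s] %s, range [%.4g, %.4g]", x$quantity,
          format(x$grid), min(x$values), max(x$values))
}

#' @export
print.volume_image <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Geometric phantom specification
#'
#' An ordered list of solid primitives, each carrying an activity
#' concentration (Bq/ml) and a linear attenuation coefficient (1/cm). Later
#' shapes override earlier ones where they overlap. Supported primitives:
#'
#' * `sphere`: `size = diameter` (mm)
#' * `cylinder`: axis along z, `size = c(radius, length)` (mm); an optional
#'   third and fourth element give an elliptic cross-section
#'   `c(rx, length, ry)` is not used -- pass `size = c(rx, ry, length)` with
#'   `elliptic = TRUE` via `shape()`'s `size` of length 3.
#' * `ellipsoid`: `size = c(ax, ay, az)` semi-axes (mm)
#' * `box`: `size = c(lx, ly, lz)` full edge lengths (mm)
#' * `dcylinder`: chamfered cylinder (axis along z), the "D"-shaped
#'   cross-section of the standard image-quality phantom shell:
#'   `size = c(r_major, r_corner, length)` -- a half-disc of radius
#'   `r_major` (y >= 0) joined to a flat-bottomed section of depth
#'   `r_corner` whose corners are rounded with radius `r_corner`.
#'
#' @param shapes List of shapes created by [shape()].
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shapes = list()) {
  structure(list(shapes = shapes), class = "phantom_spec")
}

#' @rdname phantom_spec
#' @param primitive Primitive name (see above).
#' @param center Center coordinate (mm), length 3.
#' @param size Size parameters (mm), see primitive list.
#' @param activity Activity concentration (Bq/ml, >= 0).
#' @param attenuation Linear attenuation coefficient (1/cm, >= 0).
#' @param label Optional integer label for organ/lesion maps.
#' @export
shape <- function(primitive = c("sphere", "cylinder", "ellipsoid", "box",
                                "dcylinder"),
                  center, size, activity = 0, attenuation = 0, label = NA) {
  primitive <- match.arg(primitive)
  if (activity < 0 || attenuation < 0)
    stop("activity and attenuation must be >= 0")
  if (any(size <= 0)) stop("size parameters must be > 0")
  list(primitive = primitive, center = as.numeric(center),
       size = as.numeric(size), activity = activity,
       attenuation = attenuation, label = label)
}

# Axis-aligned bounding box (mm) of a shape: list(lo, hi).
shape_bbox <- function(sh) {
  c0 <- sh$center
  half <- switch(sh$primitive,
    sphere = rep(sh$size[1] / 2, 3),
    cylinder = {
      r <- if (length(sh$size) >= 3) sh$size[1:2] else rep(sh$size[1], 2)
      len <- sh$size[length(sh$size)]
      c(r, len / 2)
    },
    ellipsoid = sh$size[1:3],
    box = sh$size[1:3] / 2,
    dcylinder = c(sh$size[1], sh$size[1], sh$size[3] / 2))
  list(lo = c0 - half, hi = c0 + half)
}

# Vectorized inside test: px, py, pz are physical coordinates (mm).
shape_inside <- function(sh, px, py, pz) {
  x <- px - sh$center[1]; y <- py - sh$center[2]; z <- pz - sh$center[3]
  switch(sh$primitive,
    sphere = {
      r <- sh$size[1] / 2
      x * x + y * y + z * z <= r * r
    },
    cylinder = {
      if (length(sh$size) >= 3) { rx <- sh$size[1]; ry <- sh$size[2]
        len <- sh$size[3]
      } else { rx <- ry <- sh$size[1]; len <- sh$size[2] }
      (x / rx)^2 + (y / ry)^2 <= 1 & abs(z) <= len / 2
    },
    ellipsoid = {
      (x / sh$size[1])^2 + (y / sh$size[2])^2 + (z / sh$size[3])^2 <= 1
    },
    box = {
      abs(x) <= sh$size[1] / 2 & abs(y) <= sh$size[2] / 2 &
        abs(z) <= sh$size[3] / 2
    },
    dcylinder = {
      R <- sh$size[1]; rc <- sh$size[2]; len <- sh$size[3]
      inz <- abs(z) <= len / 2
      upper <- y >= 0 & x * x + y * y <= R * R
      ax <- abs(x)
      lower <- y < 0 & y >= -rc &
        (ax <= R - rc | (ax - (R - rc))^2 + y * y <= rc * rc)
      inz & (upper | lower)
    })
}

# Analytic volume (mm^3) of a shape.
shape_volume <- function(sh) {
  switch(sh$primitive,
    sphere = 4 / 3 * pi * (sh$size[1] / 2)^3,
    cylinder = {
      if (length(sh$size) >= 3) pi * sh$size[1] * sh$size[2] * sh$size[3]
      else pi * sh$size[1]^2 * sh$size[2]
    },
    ellipsoid = 4 / 3 * pi * prod(sh$size[1:3]),
    box = prod(sh$size[1:3]),
    dcylinder = {
      R <- sh$size[1]; rc <- sh$size[2]
      (pi * R^2 / 2 + 2 * (R - rc) * rc + pi * rc^2 / 2) * sh$size[3]
    })
}

# Rasterize all fields of a phantom spec in one pass. Returns a list of 3D
# arrays (activity, attenuation, label, plus per-shape coverage on request).
# Each voxel is the volume-weighted mixture over a supersample^3 sub-grid;
# later shapes override earlier ones (sequential alpha-blending of the
# covered fraction, exact when the later shape sits inside the earlier one).
rasterize_fields <- function(spec, grid, supersample = 3) {
  if (supersample < 1 || supersample != round(supersample))
    stop("supersample must be an integer >= 1")
  dims <- grid_counts(grid)
  act <- array(0, dims); att <- array(0, dims); lab <- array(0L, dims)
  xs <- grid_axis_centers(grid, 1); ys <- grid_axis_centers(grid, 2)
  zs <- grid_axis_centers(grid, 3)
  d <- grid_sizes(grid)
  off <- (seq_len(supersample) - (supersample + 1) / 2) / supersample
  for (sh in spec$shapes) {
    bb <- shape_bbox(sh)
    ix <- which(xs >= bb$lo[1] - d[1] & xs <= bb$hi[1] + d[1])
    iy <- which(ys >= bb$lo[2] - d[2] & ys <= bb$hi[2] + d[2])
    iz <- which(zs >= bb$lo[3] - d[3] & zs <= bb$hi[3] + d[3])
    if (!length(ix) || !length(iy) || !length(iz)) next
    nb <- c(length(ix), length(iy), length(iz))
    px0 <- rep(xs[ix], times = nb[2] * nb[3])
    py0 <- rep(rep(ys[iy], each = nb[1]), times = nb[3])
    pz0 <- rep(zs[iz], each = nb[1] * nb[2])
    frac <- numeric(prod(nb))
    for (ox in off) for (oy in off) for (oz in off) {
      frac <- frac + shape_inside(sh, px0 + ox * d[1], py0 + oy * d[2],
                                  pz0 + oz * d[3])
    }
    frac <- frac / supersample^3
    frac <- array(frac, nb)
    sub <- act[ix, iy, iz, drop = FALSE]
    act[ix, iy, iz] <- sub * (1 - frac) + sh$activity * frac
    sub <- att[ix, iy, iz, drop = FALSE]
    att[ix, iy, iz] <- sub * (1 - frac) + sh$attenuation * frac
    if (!is.na(sh$label)) {
      labsub <- lab[ix, iy, iz, drop = FALSE]
      labsub[frac >= 0.5] <- as.integer(sh$label)
      lab[ix, iy, iz] <- labsub
    }
  }
  list(activity = act, attenuation = att, label = lab)
}

#' Rasterize a phantom specification onto a grid
#'
#' Anti-aliased rasterization: each voxel value is the volume-weighted
#' mixture of shape values evaluated on a `supersample^3` sub-grid
#' (`supersample = 1` is plain center-point assignment).
#'
#' @param spec A [phantom_spec].
#' @param grid A [voxel_grid].
#' @param supersample Sub-samples per voxel edge (integer >= 1).
#' @param field `"activity"` or `"attenuation"`.
#' @return A [volume_image].
#' @export
rasterize <- function(spec, grid, supersample = 3,
                      field = c("activity", "attenuation")) {
  field <- match.arg(field)
  f <- rasterize_fields(spec, grid, supersample)
  volume_image(f[[field]], grid, quantity = field)
}

#' NEMA image-quality phantom
#'
#' Generates the standard image-quality phantom: six fillable spheres with
#' inner diameters 10, 13, 17, 22, 28 and 37 mm, centered 5.72 cm from the
#' phantom axis on a common transaxial plane, inside a chamfered-cylinder
#' ("D"-shaped) body of interior length 180 mm whose cross-section is scaled
#' so the background cavity volume is 9575 ml. The background is filled with
#' `bg_conc` and the spheres with `sphere_conc` (defaults give the standard
#' 9.34:1 sphere-to-background concentration ratio); attenuation is uniform
#' water (`mu_water`) inside the body and zero outside. Sphere wall thickness
#' is ignored (inner diameters used directly) and no lung insert is modeled.
#'
#' @param grid A [voxel_grid]. A warning is issued if the smallest sphere is
#'   less than two voxels across.
#' @param bg_conc Background activity concentration (Bq/ml).
#' @param sphere_conc Sphere activity concentration (Bq/ml).
#' @param mu_water Water attenuation coefficient (1/cm).
#' @param supersample Rasterization supersampling factor.
#' @return A list with `activity` and `attenuation` ([volume_image]s) and
#'   `spec`, the [phantom_spec] augmented with `sphere_centers`,
#'   `sphere_diameters_mm`, `sphere_plane_z`, `bg_conc`, `sphere_conc` and
#'   `body_volume_ml`.
#' @export
make_nema_iq <- function(grid, bg_conc = 2930, sphere_conc = 27369,
                         mu_water = 0.096, supersample = 3) {
  diam <- c(10, 13, 17, 22, 28, 37)
  if (min(grid_sizes(grid)[1:2]) * 2 > min(diam))
    warning("grid too coarse to resolve the smallest sphere (< 2 voxels)")
  # Reference D cross-section: half-disc radius 147 mm over a flat-bottomed
  # chamfered section of depth 77 mm; scale transaxially to a 9575 ml cavity
  # at 180 mm interior length.
  R0 <- 147; rc0 <- 77; len <- 180
  area0 <- pi * R0^2 / 2 + 2 * (R0 - rc0) * rc0 + pi * rc0^2 / 2
  s <- sqrt((9575 * 1000 / len) / area0)
  body <- shape("dcylinder", center = c(0, 0, 0),
                size = c(R0 * s, rc0 * s, len),
                activity = bg_conc, attenuation = mu_water, label = 1)
  ang <- (0:5) * pi / 3
  centers <- cbind(57.2 * cos(ang), 57.2 * sin(ang), 0)
  spheres <- lapply(seq_along(diam), function(k)
    shape("sphere", center = centers[k, ], size = diam[k],
          activity = sphere_conc, attenuation = mu_water,
          label = 1 + k))
  spec <- phantom_spec(c(list(body), spheres))
  f <- rasterize_fields(spec, grid, supersample)
  spec$sphere_centers <- centers
  spec$sphere_diameters_mm <- diam
  spec$sphere_plane_z <- 0
  spec$body_R_mm <- R0 * s
  spec$body_rc_mm <- rc0 * s
  spec$body_len_mm <- len
  spec$bg_conc <- bg_conc
  spec$sphere_conc <- sphere_conc
  spec$body_volume_ml <- shape_volume(body) / 1000
  list(activity = volume_image(f$activity, grid, "activity"),
       attenuation = volume_image(f$attenuation, grid, "attenuation"),
       spec = spec)
}

#' Synthetic torso phantom
#'
#' A fully synthetic thorax/upper-abdomen stand-in for clinical inputs: an
#' elliptic-cylinder soft-tissue body (mu = 0.096 1/cm), two low-density
#' lungs (mu = 0.03 1/cm, low uptake), liver and spleen compartments with
#' distinct uptake, a spine rod (mu = 0.15 1/cm) and spherical lesions with
#' user-specified uptake ratios over their local background. A mild seeded
#' log-normal intra-organ texture is multiplied onto the activity. Organ
#' values are package defaults, not measurements.
#'
#' @param grid A [voxel_grid].
#' @param seed Integer seed; the same seed reproduces the volumes exactly.
#' @param lesions List of lesions, each `list(center = c(x, y, z) mm,
#'   diameter = mm, uptake = ratio over local background)`.
#' @param bg_activity Soft-tissue background activity (Bq/ml).
#' @param texture_sd Log-scale SD of the intra-organ texture (0 disables).
#' @return A list with `activity`, `attenuation` ([volume_image]s) and
#'   `labels` (integer array: 1 body, 2/3 lungs, 4 liver, 5 spleen, 6 spine,
#'   10+k for lesion k).
#' @export
make_synthetic_torso <- function(grid, seed = 1, lesions = list(),
                                 bg_activity = 3000, texture_sd = 0.1) {
  d <- grid_sizes(grid)
  for (le in lesions)
    if (le$diameter < 2 * min(d[1:2]))
      stop("lesion diameters must be at least 2 voxels")
  ext <- grid_counts(grid) * d
  zlen <- min(240, ext[3] * 0.95)
  organs <- list(
    body  = shape("cylinder", c(0, 0, 0), c(160, 110, zlen),
                  activity = bg_activity, attenuation = 0.096, label = 1),
    lungL = shape("ellipsoid", c(-65, 15, zlen * 0.15), c(48, 65, zlen * 0.32),
                  activity = 0.25 * bg_activity, attenuation = 0.03,
                  label = 2),
    lungR = shape("ellipsoid", c(65, 15, zlen * 0.15), c(48, 65, zlen * 0.32),
                  activity = 0.25 * bg_activity, attenuation = 0.03,
                  label = 3),
    liver = shape("ellipsoid", c(55, -20, -zlen * 0.22),
                  c(75, 60, zlen * 0.22),
                  activity = 2.2 * bg_activity, attenuation = 0.096,
                  label = 4),
    spleen = shape("ellipsoid", c(-85, -25, -zlen * 0.2),
                   c(35, 30, zlen * 0.15),
                   activity = 1.6 * bg_activity, attenuation = 0.096,
                   label = 5),
    spine = shape("cylinder", c(0, -75, 0), c(16, 16, zlen * 0.95),
                  activity = 0.6 * bg_activity, attenuation = 0.15,
                  label = 6))
  spec0 <- phantom_spec(unname(organs))
  base <- rasterize_fields(spec0, grid, supersample = 2)
  # Lesion uptake is relative to the local background taken at the lesion
  # center from the organ map; overlapping lesions resolve last-wins.
  lesion_shapes <- list()
  occupied <- list()
  for (k in seq_along(lesions)) {
    le <- lesions[[k]]
    ctr <- as.numeric(le$center)
    idx <- pmin(pmax(round((ctr - grid$origin) / d) + 1, 1), grid_counts(grid))
    local_bg <- base$activity[idx[1], idx[2], idx[3]]
    if (local_bg <= 0) local_bg <- bg_activity
    for (pv in occupied)
      if (sqrt(sum((pv$center - ctr)^2)) < (pv$diameter + le$diameter) / 2)
        warning("overlapping lesions: later lesion overrides earlier one")
    occupied[[length(occupied) + 1]] <- list(center = ctr,
                                             diameter = le$diameter)
    lesion_shapes[[k]] <- shape("sphere", ctr, le$diameter,
                                activity = le$uptake * local_bg,
                                attenuation = 0.096, label = 10 + k)
  }
  spec <- phantom_spec(c(unname(organs), lesion_shapes))
  f <- rasterize_fields(spec, grid, supersample = 2)
  act <- f$activity
  if (texture_sd > 0) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(as.integer(seed))
    noise <- array(stats::rnorm(prod(grid_counts(grid))), grid_counts(grid))
    noise <- gaussian_smooth_3d(noise, sigma_vox = rep(1.5, 3))
    noise <- noise / stats::sd(noise)
    act <- act * exp(texture_sd * noise - texture_sd^2 / 2)
  }
  list(activity = volume_image(act, grid, "activity"),
       attenuation = volume_image(f$attenuation, grid, "attenuation"),
       labels = f$label)
}
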