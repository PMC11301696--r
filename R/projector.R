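# Counts-preserving Joseph-method forward/back projector.
#
# Lines of response are parameterized directly in sinogram coordinates: the
# LOR for (radial bin s, view phi) is the line through (s cos phi, s sin phi)
# with direction (-sin phi, cos phi). Each axial sinogram plane is treated as
# an in-plane (direct) 2D projection at its axial position; image slices are
# mixed onto planes by linear interpolation weights. The whole operator is
# realized as a sparse matrix so the back-projector is its exact transpose
# and adjointness holds to machine precision.
#
# Two normalizations of the same geometric weights are kept:
#  * A_geo: plain Joseph line-integral weights in mm, used for attenuation
#    line integrals (physical units).
#  * A_cnt: per-voxel (column) normalized so every voxel's total contribution
#    over all LORs and planes is exactly 1 -- the counts-preserving
#    convention: each simulated decay is allocated once across the sinogram,
#    which makes total counts exactly linear in activity, time and
#    sensitivity.

.petsim_cache <- new.env(parent = emptyenv())

projector_key <- function(g, grid) {
  paste(c(g$n_projections, g$n_views, g$n_planes, g$n_tof_bins,
          g$tof_bin_width_ps, g$timing_resolution_ps, g$ring_radius_mm,
          g$fov_transaxial_mm, g$fov_axial_mm,
          grid_counts(grid), grid_sizes(grid), grid$origin),
        collapse = "|")
}

# Joseph weights for the 2D transaxial system, one view at a time.
# Returns triplets (row, col, w_mm, t_mm) where t is the signed emission
# position along the LOR (used by the TOF kernel).
build_joseph_triplets <- function(g, grid) {
  nproj <- g$n_projections
  soff <- radial_offsets(g)
  phis <- view_angles(g)
  xc <- grid_axis_centers(grid, 1); yc <- grid_axis_centers(grid, 2)
  nx <- grid$nx; ny <- grid$ny
  dx <- grid$dx; dy <- grid$dy
  acc_i <- vector("list", length(phis)); acc_j <- acc_i
  acc_x <- acc_i; acc_t <- acc_i
  for (v in seq_along(phis)) {
    phi <- phis[v]; sn <- sin(phi); cs <- cos(phi)
    rowbase <- (v - 1L) * nproj + seq_len(nproj)
    if (abs(sn) >= abs(cs)) {
      # dominant axis x: sample at voxel-center x planes, interpolate in y
      w0 <- dx / abs(sn)
      pos <- outer(soff / sn, -xc * (cs / sn), "+")     # y at each (s, x)
      tpar <- outer(soff * (cs / sn), -xc / sn, "+")    # position along LOR
      fy <- (pos - yc[1]) / dy
      i0 <- floor(fy); fr <- fy - i0
      nb0 <- i0 + 1L; nb1 <- i0 + 2L                    # 1-based y indices
      rows <- matrix(rowbase, nproj, nx)
      stepidx <- matrix(rep(seq_len(nx), each = nproj), nproj, nx)
      col0 <- stepidx + (nb0 - 1L) * nx
      col1 <- stepidx + (nb1 - 1L) * nx
      ok0 <- nb0 >= 1L & nb0 <= ny
      ok1 <- nb1 >= 1L & nb1 <= ny
      w_0 <- w0 * (1 - fr); w_1 <- w0 * fr
    } else {
      # dominant axis y: sample at voxel-center y planes, interpolate in x
      w0 <- dy / abs(cs)
      pos <- outer(soff / cs, -yc * (sn / cs), "+")     # x at each (s, y)
      tpar <- outer(-soff * (sn / cs), yc / cs, "+")
      fx <- (pos - xc[1]) / dx
      i0 <- floor(fx); fr <- fx - i0
      nb0 <- i0 + 1L; nb1 <- i0 + 2L                    # 1-based x indices
      rows <- matrix(rowbase, nproj, ny)
      stepidx <- matrix(rep(seq_len(ny), each = nproj), nproj, ny)
      col0 <- nb0 + (stepidx - 1L) * nx
      col1 <- nb1 + (stepidx - 1L) * nx
      ok0 <- nb0 >= 1L & nb0 <= nx
      ok1 <- nb1 >= 1L & nb1 <= nx
      w_0 <- w0 * (1 - fr); w_1 <- w0 * fr
    }
    keep0 <- ok0 & w_0 > 0; keep1 <- ok1 & w_1 > 0
    acc_i[[v]] <- c(rows[keep0], rows[keep1])
    acc_j[[v]] <- c(col0[keep0], col1[keep1])
    acc_x[[v]] <- c(w_0[keep0], w_1[keep1])
    acc_t[[v]] <- c(tpar[keep0], tpar[keep1])
  }
  list(i = unlist(acc_i), j = unlist(acc_j), x = unlist(acc_x),
       t = unlist(acc_t),
       nrow = nproj * g$n_views, ncol = nx * ny)
}

# Axial slice -> plane interpolation matrix (n_planes x nz). Rows sum to 1
# (each plane is the linear interpolation of the two bracketing image
# slices, clamped at the ends).
build_axial_interp <- function(g, grid) {
  zp <- plane_z_positions(g)
  zs <- grid_axis_centers(grid, 3)
  nz <- grid$nz
  if (nz == 1) {
    P <- Matrix::sparseMatrix(i = seq_along(zp), j = rep(1L, length(zp)),
                              x = rep(1, length(zp)),
                              dims = c(length(zp), 1L))
    return(P)
  }
  fz <- (zp - zs[1]) / grid$dz
  fz <- pmin(pmax(fz, 0), nz - 1)
  k0 <- pmin(floor(fz), nz - 2)
  fr <- fz - k0
  i <- rep(seq_along(zp), 2L)
  j <- c(k0 + 1, k0 + 2)
  x <- c(1 - fr, fr)
  keep <- x > 0
  Matrix::sparseMatrix(i = i[keep], j = j[keep], x = x[keep],
                       dims = c(length(zp), nz))
}

col_normalize <- function(M) {
  cs <- Matrix::colSums(M)
  inv <- ifelse(cs > 0, 1 / cs, 0)
  M %*% Matrix::Diagonal(x = inv)
}

# Build (or fetch from cache) the full projector bundle for a geometry/grid.
get_projector <- function(g, grid) {
  key <- projector_key(g, grid)
  P <- .petsim_cache[[key]]
  if (!is.null(P)) return(P)
  trip <- build_joseph_triplets(g, grid)
  A_geo <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                                dims = c(trip$nrow, trip$ncol))
  c2d <- Matrix::colSums(A_geo)
  A_cnt <- col_normalize(A_geo)
  P_interp <- build_axial_interp(g, grid)
  P_cnt <- col_normalize(P_interp)
  P <- list(A_geo = A_geo, A_cnt = A_cnt, c2d = c2d,
            P_interp = P_interp, P_cnt = P_cnt, trip = trip,
            geometry = g, grid = grid, tof_mats = NULL)
  .petsim_cache[[key]] <- P
  key_obj <- key
  P$key <- key_obj
  .petsim_cache[[key]] <- P
  P
}

# TOF bin edges along the LOR (mm). Bin b covers [edges[b], edges[b+1]].
tof_edges_mm <- function(g) {
  c_mm_ps <- 0.299792458
  dl <- c_mm_ps * g$tof_bin_width_ps / 2
  n <- g$n_tof_bins
  (-(n / 2) + 0:n) * dl
}

tof_sigma_mm <- function(g) {
  0.299792458 * g$timing_resolution_ps / 2 / (2 * sqrt(2 * log(2)))
}

# Per-TOF-bin counts matrices: sum over bins equals A_cnt exactly (the
# Gaussian kernel is renormalized per emission point over the covered bins).
get_tof_matrices <- function(g, grid) {
  P <- get_projector(g, grid)
  if (!is.null(P$tof_mats)) return(P$tof_mats)
  trip <- P$trip
  edges <- tof_edges_mm(g)
  sig <- tof_sigma_mm(g)
  t <- trip$t
  cum <- vapply(edges, function(e) stats::pnorm((e - t) / sig),
                numeric(length(t)))
  wsum <- cum[, ncol(cum)] - cum[, 1]
  wsum[wsum <= 0] <- 1
  xc <- trip$x / pmax(P$c2d[trip$j], .Machine$double.xmin)
  mats <- vector("list", g$n_tof_bins)
  for (b in seq_len(g$n_tof_bins)) {
    wb <- (cum[, b + 1] - cum[, b]) / wsum
    keep <- wb > 1e-12
    mats[[b]] <- Matrix::sparseMatrix(i = trip$i[keep], j = trip$j[keep],
                                      x = xc[keep] * wb[keep],
                                      dims = c(trip$nrow, trip$ncol))
  }
  P$tof_mats <- mats
  .petsim_cache[[projector_key(g, grid)]] <- P
  mats
}

#' Sinogram container
#'
#' @param values Array indexed `(projection, view, plane[, tof_bin])`.
#' @param geometry A [scanner_geometry].
#' @param tof Logical: does the array carry a TOF dimension?
#' @return An object of class `sinogram`.
#' @export
sinogram <- function(values, geometry, tof = FALSE) {
  expect <- c(geometry$n_projections, geometry$n_views, geometry$n_planes)
  if (tof) expect <- c(expect, geometry$n_tof_bins)
  if (!identical(dim(values), as.integer(expect)))
    stop("sinogram shape does not match geometry")
  structure(list(values = values, geometry = geometry, tof = tof),
            class = "sinogram")
}

#' @export
format.sinogram <- function(x, ...) {
  sprintf("sinogram %s [%s], total %.6g",
          paste(dim(x$values), collapse = "x"), x$geometry$name,
          sum(x$values))
}

#' @export
print.sinogram <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

check_bore <- function(g, grid) {
  v <- validate_geometry(g, grid)
  bore <- grep("bore", v, value = TRUE)
  if (length(bore)) stop(bore[1])
}

img_as_matrix <- function(img) {
  v <- img$values
  dim(v) <- c(img$grid$nx * img$grid$ny, img$grid$nz)
  v
}

#' Forward projection (Joseph's method, counts-preserving)
#'
#' Computes line integrals of the image along every LOR by Joseph's method
#' (linear interpolation perpendicular to the dominant axis; ties between
#' dominant axes broken toward x), normalized per voxel so that for any
#' non-attenuated image the total sinogram value equals the total image
#' value. With `tof = TRUE` each emission point's contribution is spread
#' over the TOF bins by a Gaussian kernel whose width derives from the
#' timing resolution, renormalized per point so the TOF-summed sinogram
#' reproduces the non-TOF one.
#'
#' @param img A [volume_image] with non-negative values; its grid must fit
#'   inside the scanner bore.
#' @param g A [scanner_geometry].
#' @param tof Logical, spread counts over TOF bins.
#' @return A [sinogram] of counts-like values.
#' @export
forward_project <- function(img, g, tof = FALSE) {
  check_bore(g, img$grid)
  if (any(img$values < 0)) stop("forward_project requires non-negative input")
  P <- get_projector(g, img$grid)
  Y <- img_as_matrix(img) %*% Matrix::t(P$P_cnt)   # voxels2d x planes
  if (!tof) {
    S <- as.matrix(P$A_cnt %*% Y)
    return(sinogram(array(S, c(g$n_projections, g$n_views, g$n_planes)),
                    g, tof = FALSE))
  }
  mats <- get_tof_matrices(g, img$grid)
  out <- array(0, c(g$n_projections, g$n_views, g$n_planes, g$n_tof_bins))
  for (b in seq_len(g$n_tof_bins))
    out[, , , b] <- as.matrix(mats[[b]] %*% Y)
  sinogram(out, g, tof = TRUE)
}

#' Back projection (exact adjoint of the forward projector)
#'
#' @param s A [sinogram].
#' @param g A [scanner_geometry]; must match the sinogram's geometry.
#' @param grid Target [voxel_grid].
#' @return A [volume_image] (quantity `"reconstructed"`).
#' @export
back_project <- function(s, g, grid) {
  if (!identical(format(s$geometry), format(g)))
    stop("sinogram geometry does not match the supplied geometry")
  P <- get_projector(g, grid)
  nlor <- g$n_projections * g$n_views
  if (!s$tof) {
    S2 <- s$values; dim(S2) <- c(nlor, g$n_planes)
    Y <- Matrix::crossprod(P$A_cnt, S2)
  } else {
    mats <- get_tof_matrices(g, grid)
    Y <- 0
    for (b in seq_len(g$n_tof_bins)) {
      S2 <- s$values[, , , b]; dim(S2) <- c(nlor, g$n_planes)
      Y <- Y + Matrix::crossprod(mats[[b]], S2)
    }
  }
  X <- as.matrix(Y %*% P$P_cnt)
  dim(X) <- grid_counts(grid)
  volume_image(X, grid, quantity = "reconstructed")
}

#' Attenuation factor sinogram
#'
#' Per-LOR survival probability `exp(-integral of mu dl)` with the line
#' integral in physical units (mm path lengths, mu in 1/cm). No
#' counts-normalization is applied to this integral.
#'
#' @param mu A [volume_image] of attenuation coefficients (1/cm, >= 0).
#' @param g A [scanner_geometry].
#' @return A non-TOF [sinogram] with values in (0, 1].
#' @export
attenuation_factors <- function(mu, g) {
  if (any(mu$values < 0)) stop("attenuation map must be non-negative")
  P <- get_projector(g, mu$grid)
  L <- as.matrix((P$A_geo %*% img_as_matrix(mu)) %*% Matrix::t(P$P_interp))
  f <- exp(-L / 10)  # mm * cm^-1 -> dimensionless
  sinogram(array(f, c(g$n_projections, g$n_views, g$n_planes)), g,
           tof = FALSE)
}
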