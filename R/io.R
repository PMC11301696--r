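# Volume and sinogram file formats plus the run manifest.
#
# Two volume dialects are supported: NIfTI (via RNifti) and a raw binary
# dialect -- little-endian 32-bit float, x fastest -- accompanied by a plain
# text header documenting dimensions, voxel size, origin, quantity and
# units.

raw_header_path <- function(path) {
  sub("\\.raw$", ".hdr", path)
}

#' Write a volume image
#'
#' Format is chosen from the extension: `.nii` / `.nii.gz` (NIfTI, voxel
#' sizes and origin stored in the sform) or `.raw` (little-endian float32,
#' x fastest, plus a `.hdr` text header with dimensions, voxel size, origin,
#' quantity and units).
#'
#' @param img A [volume_image].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_volume <- function(img, path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    ni <- RNifti::asNifti(array(as.numeric(img$values),
                                grid_counts(img$grid)))
    RNifti::pixdim(ni) <- grid_sizes(img$grid)
    aff <- diag(c(grid_sizes(img$grid), 1))
    aff[1:3, 4] <- img$grid$origin
    ni <- RNifti::`sform<-`(ni, structure(aff, code = 2L))
    RNifti::writeNifti(ni, path)
  } else if (grepl("\\.raw$", path)) {
    con <- file(path, "wb")
    writeBin(as.numeric(img$values), con, size = 4, endian = "little")
    close(con)
    units <- switch(img$quantity, activity = "Bq/ml",
                    attenuation = "1/cm", reconstructed = "Bq/ml")
    writeLines(c(
      sprintf("dims = %d %d %d", img$grid$nx, img$grid$ny, img$grid$nz),
      sprintf("voxel_size_mm = %.10g %.10g %.10g", img$grid$dx,
              img$grid$dy, img$grid$dz),
      sprintf("origin_mm = %.10g %.10g %.10g", img$grid$origin[1],
              img$grid$origin[2], img$grid$origin[3]),
      paste0("quantity = ", img$quantity),
      paste0("units = ", units),
      "datatype = float32",
      "byte_order = little-endian",
      "axis_order = x-fastest"), raw_header_path(path))
  } else stop("unsupported volume format: ", path)
  invisible(path)
}

#' Read a volume image
#'
#' @param path `.nii` / `.nii.gz` or `.raw` path (the raw dialect expects
#'   the matching `.hdr` text header next to it).
#' @param quantity Override the stored quantity (required for NIfTI if not
#'   `"activity"`).
#' @return A [volume_image].
#' @export
read_volume <- function(path, quantity = NULL) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    ni <- RNifti::readNifti(path)
    d <- RNifti::pixdim(ni)
    aff <- RNifti::xform(ni)
    org <- aff[1:3, 4]
    vals <- array(as.numeric(ni), dim(ni))
    grid <- voxel_grid(dim(ni)[1], dim(ni)[2], dim(ni)[3],
                       d[1], d[2], d[3], origin = org)
    if (is.null(quantity)) {
      warning("NIfTI carries no quantity; defaulting to activity")
      quantity <- "activity"
    }
    return(volume_image(vals, grid, quantity))
  }
  if (!grepl("\\.raw$", path)) stop("unsupported volume format: ", path)
  hdr <- read_keyvalue(raw_header_path(path))
  dims <- as.integer(strsplit(hdr$dims, "\\s+")[[1]])
  sizes <- as.numeric(strsplit(hdr$voxel_size_mm, "\\s+")[[1]])
  org <- as.numeric(strsplit(hdr$origin_mm, "\\s+")[[1]])
  expected <- prod(dims) * 4
  actual <- file.size(path)
  if (is.na(actual) || actual != expected)
    stop(sprintf("data size mismatch: header implies %d bytes, file has %d",
                 expected, actual))
  con <- file(path, "rb")
  vals <- readBin(con, numeric(), n = prod(dims), size = 4,
                  endian = "little")
  close(con)
  q <- if (!is.null(quantity)) quantity else hdr$quantity
  if (is.null(q) || !q %in% c("activity", "attenuation", "reconstructed")) {
    warning("unknown quantity in header; defaulting to activity")
    q <- "activity"
  }
  grid <- voxel_grid(dims[1], dims[2], dims[3], sizes[1], sizes[2], sizes[3],
                     origin = org)
  volume_image(array(vals, dims), grid, q)
}

#' Write / read a sinogram in the raw binary dialect
#'
#' Little-endian float32, projection fastest, then view, plane, TOF bin;
#' the text header names the geometry preset so the sinogram can be
#' re-attached to its geometry.
#'
#' @param s A [sinogram].
#' @param path Output `.raw` path.
#' @param geometry Optional geometry (list with `geometry`) overriding the
#'   preset named in the header on read.
#' @return `read_sinogram` returns a [sinogram].
#' @export
write_sinogram <- function(s, path) {
  con <- file(path, "wb")
  writeBin(as.numeric(s$values), con, size = 4, endian = "little")
  close(con)
  writeLines(c(
    sprintf("dims = %s", paste(dim(s$values), collapse = " ")),
    paste0("geometry = ", s$geometry$name),
    paste0("tof = ", if (s$tof) "1" else "0"),
    "datatype = float32",
    "byte_order = little-endian",
    "axis_order = projection-fastest"), raw_header_path(path))
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path, geometry = NULL) {
  hdr <- read_keyvalue(raw_header_path(path))
  dims <- as.integer(strsplit(hdr$dims, "\\s+")[[1]])
  g <- if (!is.null(geometry)) geometry$geometry
       else resolve_geometry(hdr$geometry)$geometry
  expected <- prod(dims) * 4
  actual <- file.size(path)
  if (is.na(actual) || actual != expected)
    stop(sprintf("data size mismatch: header implies %d bytes, file has %d",
                 expected, actual))
  con <- file(path, "rb")
  vals <- readBin(con, numeric(), n = prod(dims), size = 4,
                  endian = "little")
  close(con)
  sinogram(array(vals, dims), g, tof = identical(hdr$tof, "1"))
}

#' Write a run manifest
#'
#' JSON snapshot of everything needed to reproduce a run bit-for-bit on the
#' same platform: configuration, seeds, geometry preset, per-stage wall
#' time, per-component count totals and the package version.
#'
#' @param manifest Named list.
#' @param path Output `.json` path.
#' @export
write_manifest <- function(manifest, path) {
  manifest$software_version <- as.character(utils::packageVersion("petsim"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
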