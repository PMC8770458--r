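#' Anisotropic voxel geometry
#'
#' Describes the raster grid of a 3-D acquisition: voxel counts per axis
#' and the physical voxel size in nanometres.  The default voxel size is
#' the serial block-face SEM sampling used throughout the package,
#' 13.5 x 13.5 nm in-plane with 50 nm slice steps.
#'
#' @param dims integer vector of length 3, voxel counts along x, y, z.
#' @param size_nm numeric vector of length 3, voxel edge lengths in nm.
#' @return An object of class `voxel_geometry`.
#' @examples
#' voxel_geometry(c(128, 128, 32))
#' @export
voxel_geometry <- function(dims, size_nm = c(13.5, 13.5, 50)) {
  dims <- as.integer(dims)
  size_nm <- as.numeric(size_nm)
  if (length(dims) != 3L || any(is.na(dims)) || any(dims < 1L))
    stop("`dims` must be three integers >= 1")
  if (length(size_nm) != 3L || any(!is.finite(size_nm)) || any(size_nm <= 0))
    stop("`size_nm` must be three positive lengths (nm)")
  structure(list(dims = dims, size_nm = size_nm), class = "voxel_geometry")
}

#' Scale a voxel geometry
#'
#' Multiplies the physical voxel size by a constant factor while keeping
#' the voxel counts, e.g. to make a reduced raster span the physical
#' extent of a full acquisition.
#'
#' @param geom a [voxel_geometry()].
#' @param factor positive scale factor applied to the voxel size.
#' @return A `voxel_geometry`.
#' @export
scale_geometry <- function(geom, factor) {
  stopifnot(inherits(geom, "voxel_geometry"), is.numeric(factor),
            length(factor) == 1L, factor > 0)
  voxel_geometry(geom$dims, geom$size_nm * factor)
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf("voxel geometry: %d x %d x %d voxels, %.6g x %.6g x %.6g nm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$size_nm[1], x$size_nm[2], x$size_nm[3]))
  invisible(x)
}

# voxel volume in nm^3
voxel_volume_nm3 <- function(geom) prod(geom$size_nm)
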