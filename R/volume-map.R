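#' Volumetric density map on a cubic lattice
#'
#' A `volume_map` stores a scalar density field sampled on a cubic lattice.
#' The lattice is described by a single voxel spacing `width` (Angstrom), the
#' physical position `origin` of the first voxel (voxel `(0,0,0)`, 0-based),
#' and the voxel counts `dims = (NX, NY, NZ)`. Densities are held in a 3D
#' array whose first index runs along x, so the flattened vector is ordered
#' with x changing fastest and z slowest -- the on-disk order of the Situs
#' ASCII format.
#'
#' The physical position of voxel `(i,j,k)` (0-based) is
#' `origin + width * c(i,j,k)`.
#'
#' @param data numeric 3D array, or a vector of length `prod(dims)` in
#'   x-fastest order together with `dims`.
#' @param width voxel spacing in Angstrom; must be positive.
#' @param origin numeric length-3, physical coordinate of the first voxel.
#' @param dims integer length-3 voxel counts, required when `data` is a
#'   plain vector.
#' @return An object of class `volume_map`.
#' @examples
#' m <- volume_map(array(1, c(4, 4, 4)), width = 2, origin = c(0, 0, 0))
#' total_density(m)
#' @export
volume_map <- function(data, width, origin = c(0, 0, 0), dims = NULL) {
  if (!is.null(dims)) {
    dims <- as.integer(dims)
    if (length(dims) != 3L || any(dims < 1L))
      stop("dims must be three counts >= 1")
    if (length(data) != prod(dims))
      stop("data length ", length(data), " does not match dims ",
           paste(dims, collapse = "x"))
    data <- array(as.numeric(data), dim = dims)
  }
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a 3D array (or a vector with dims supplied)")
  if (!is.numeric(width) || length(width) != 1L || !is.finite(width) || width <= 0)
    stop("width must be a single positive number")
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop("origin must be three finite coordinates")
  structure(
    list(width = as.numeric(width), origin = as.numeric(origin),
         dims = as.integer(dim(data)), data = data),
    class = "volume_map")
}

#' @export
print.volume_map <- function(x, ...) {
  cat(sprintf("volume_map: %d x %d x %d voxels, width %.4g A\n",
              x$dims[1], x$dims[2], x$dims[3], x$width))
  cat(sprintf("  origin (%.3f, %.3f, %.3f) A\n",
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  density min %.4g  max %.4g  mean %.4g\n",
              min(x$data), max(x$data), mean(x$data)))
  invisible(x)
}

#' Lattice axis coordinates of a map
#'
#' Physical coordinates of the voxel centers along each axis.
#'
#' @param map a `volume_map`.
#' @return List with numeric vectors `x`, `y`, `z`.
#' @export
voxel_axes <- function(map) {
  stopifnot(inherits(map, "volume_map"))
  list(x = map$origin[1] + map$width * (seq_len(map$dims[1]) - 1),
       y = map$origin[2] + map$width * (seq_len(map$dims[2]) - 1),
       z = map$origin[3] + map$width * (seq_len(map$dims[3]) - 1))
}

#' Physical position of voxels
#'
#' @param map a `volume_map`.
#' @param ijk integer matrix (n x 3) of 0-based voxel indices.
#' @return n x 3 matrix of coordinates in Angstrom.
#' @export
voxel_position <- function(map, ijk) {
  stopifnot(inherits(map, "volume_map"))
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  sweep(ijk * map$width, 2, map$origin, "+")
}

#' Total density of a map
#'
#' Sum of all voxel values (an unnormalized integral; multiply by `width^3`
#' for the volume integral).
#'
#' @param map a `volume_map`.
#' @return Scalar sum of densities.
#' @export
total_density <- function(map) {
  stopifnot(inherits(map, "volume_map"))
  sum(map$data)
}

# Strict lattice identity used by voxel-wise algebra and correlation scoring.
same_lattice <- function(a, b, tol = 1e-6) {
  inherits(a, "volume_map") && inherits(b, "volume_map") &&
    all(a$dims == b$dims) &&
    abs(a$width - b$width) <= tol * a$width &&
    all(abs(a$origin - b$origin) <= tol * max(a$width, 1))
}

stop_lattice_mismatch <- function(a, b) {
  if (!same_lattice(a, b))
    stop("maps are not on the same lattice (width/dims/origin differ); ",
         "use resample_to() for deliberate registration")
  invisible(TRUE)
}
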