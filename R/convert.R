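#' Rasterize an atomic model into a density map (pdb2vol)
#'
#' Real-space resolution lowering in two stages: (1) each atom's weight
#' (unit weight, or its approximate atomic mass with `mass_weighting`) is
#' distributed over the eight surrounding voxels by trilinear interpolation;
#' (2) the resulting lattice is convolved with the chosen point-spread
#' kernel. The map is padded by the kernel truncation radius so the
#' convolution never clips, and the origin is shifted accordingly.
#'
#' The result carries attributes `total_weight` (trilinear-projected weight,
#' equal to the number of atoms or the total mass) and `kernel_sum` (sum of
#' the rasterized kernel), so that `sum(map$data) = total_weight * kernel_sum`.
#'
#' @param model an [atomic_model] or bead model.
#' @param width voxel spacing in Angstrom.
#' @param kernel a [kernels] object; for a Gaussian, a resolution at least
#'   `2 * width` is recommended (a warning is given below that).
#' @param mass_weighting if `TRUE`, weight atoms by approximate element
#'   mass (from the first letter of the atom name); default all-unit weights.
#' @param weighting atom weights: `"unit"` (default), `"mass"`, or
#'   `"occupancy"` (use the occupancy field, e.g. for densities encoded by
#'   [vol2pdb()]); `mass_weighting = TRUE` is shorthand for `"mass"`.
#' @param lattice optional list `(origin, dims)` forcing rasterization onto
#'   an existing lattice (used when scoring against a target map); no extra
#'   padding is added and atoms outside the lattice lose their weight.
#' @return A [volume_map].
#' @seealso [vol2pdb()], [beads2vol()]
#' @export
pdb2vol <- function(model, width, kernel = gaussian_kernel(resolution = 3 * width),
                    mass_weighting = FALSE, lattice = NULL,
                    weighting = c("unit", "mass", "occupancy")) {
  if (inherits(model, "bead_model")) model <- as_atomic_model(model)
  stopifnot(inherits(model, "atomic_model"))
  if (nrow(model) == 0) stop("empty model")
  if (!is.numeric(width) || width <= 0) stop("width must be positive")
  if (kernel$family == "gaussian" && kernel$params$resolution < 2 * width)
    warning("Gaussian resolution ", signif(kernel$params$resolution, 4),
            " A is below 2 * width; the kernel is undersampled")
  weighting <- match.arg(weighting)
  if (mass_weighting) weighting <- "mass"
  w <- switch(weighting,
              unit = rep(1, nrow(model)),
              mass = element_masses(model$elety),
              occupancy = model$o)
  kern <- rasterize_kernel(kernel, width)
  K <- (dim(kern)[1] - 1L) %/% 2L
  xyz <- coords(model)
  if (is.null(lattice)) {
    lo <- apply(xyz, 2, min)
    hi <- apply(xyz, 2, max)
    origin <- lo - (K + 1) * width
    dims <- floor((hi - origin) / width) + 2L + K + 1L
  } else {
    origin <- lattice$origin
    dims <- as.integer(lattice$dims)
  }
  lat <- trilinear_project(xyz, w, origin, width, dims)
  dat <- convolve_lattice(lat, kern)
  out <- volume_map(dat, width = width, origin = origin)
  attr(out, "total_weight") <- sum(w)
  attr(out, "kernel_sum") <- sum(kern)
  out
}

# Distribute point weights onto the 8 surrounding voxels of a lattice.
trilinear_project <- function(xyz, w, origin, width, dims) {
  f <- sweep(xyz, 2, origin) / width
  i0 <- floor(f)
  fr <- f - i0
  lat <- numeric(prod(dims))
  for (corner in 0:7) {
    dx <- corner %% 2
    dy <- (corner %/% 2) %% 2
    dz <- corner %/% 4
    ii <- i0[, 1] + dx; jj <- i0[, 2] + dy; kk <- i0[, 3] + dz
    wt <- w *
      (dx * fr[, 1] + (1 - dx) * (1 - fr[, 1])) *
      (dy * fr[, 2] + (1 - dy) * (1 - fr[, 2])) *
      (dz * fr[, 3] + (1 - dz) * (1 - fr[, 3]))
    ok <- ii >= 0 & ii < dims[1] & jj >= 0 & jj < dims[2] &
      kk >= 0 & kk < dims[3] & wt != 0
    if (!any(ok)) next
    idx <- 1 + ii[ok] + dims[1] * (jj[ok] + dims[2] * kk[ok])
    acc <- rowsum(wt[ok], idx)
    lat[as.numeric(rownames(acc))] <- lat[as.numeric(rownames(acc))] + acc[, 1]
  }
  array(lat, dim = dims)
}

element_masses <- function(elety) {
  tab <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
           S = 32.06, FE = 55.845, ZN = 65.38, MG = 24.305, CA = 40.078)
  # first alphabetic character of the atom name approximates the element
  el <- toupper(substr(gsub("[^A-Za-z].*$", "", trimws(elety)), 1, 1))
  m <- tab[el]
  m[is.na(m)] <- mean(tab[c("C", "N", "O")])
  unname(m)
}

#' Encode a density map as pseudo-atoms (vol2pdb)
#'
#' Each voxel with density above `max(0, threshold)` becomes one
#' pseudo-atom at the voxel's physical position, with the density written
#' to the occupancy field. Atoms are ordered x-fastest, matching the map
#' storage order. This frees a map from its cubic lattice so it can be
#' rotated and translated as a docking probe.
#'
#' @param map a [volume_map].
#' @param threshold density threshold; voxels must exceed `max(0, threshold)`.
#' @return An [atomic_model] of pseudo-atoms.
#' @export
vol2pdb <- function(map, threshold = 0) {
  stopifnot(inherits(map, "volume_map"))
  lvl <- max(0, threshold)
  sel <- which(as.vector(map$data) > lvl)
  if (length(sel) == 0) stop("no voxel above threshold ", lvl)
  ijk <- arrayInd(sel, map$dims) - 1L
  pos <- voxel_position(map, ijk)
  atomic_model(pos[, 1], pos[, 2], pos[, 3], elety = "CA", resid = "VOL",
               chain = "A", o = as.vector(map$data)[sel], b = 0)
}

#' Project an atomic structure onto an HCP bead model (pdb2sax)
#'
#' Overlays a hexagonal close-packed lattice with center spacing
#' `2 * bead_radius` (sphere contact) on the model and keeps every lattice
#' site with at least one atom within `bead_radius` of its center. The
#' close-packed planes are normal to z with ABAB stacking, and the lattice
#' phase is anchored so that one site coincides with the atom centroid (the
#' published tool does not print its phasing; both the keep rule and the
#' anchor are configurable through `anchor`).
#'
#' @param model an [atomic_model].
#' @param bead_radius bead radius in Angstrom; also written to the PDB
#'   occupancy field on export.
#' @param anchor lattice phase anchor (a point coinciding with a lattice
#'   site); default the atom centroid.
#' @return A `bead_model`: data frame of bead centers with attribute
#'   `bead_radius`.
#' @export
pdb2sax <- function(model, bead_radius, anchor = NULL) {
  stopifnot(inherits(model, "atomic_model"))
  if (nrow(model) == 0) stop("empty model")
  if (bead_radius <= 0) stop("bead_radius must be positive")
  if (is.null(anchor)) anchor <- centroid(model)
  a <- 2 * bead_radius
  xyz <- coords(model)
  lo <- apply(xyz, 2, min) - bead_radius
  hi <- apply(xyz, 2, max) + bead_radius
  sites <- hcp_sites(lo, hi, a, anchor)
  keep <- min_dist_within(sites, xyz, bead_radius)
  if (!any(keep)) stop("no lattice site within bead_radius of any atom")
  sites <- sites[keep, , drop = FALSE]
  structure(
    data.frame(x = sites[, 1], y = sites[, 2], z = sites[, 3]),
    bead_radius = bead_radius,
    class = c("bead_model", "data.frame"))
}

# Enumerate HCP lattice sites covering the box [lo, hi]: triangular layers
# normal to z, ABAB stacking, nearest-neighbor spacing a, phased so that an
# A-layer site sits at `anchor`.
hcp_sites <- function(lo, hi, a, anchor) {
  dz <- a * sqrt(2 / 3)              # interlayer spacing
  ry <- a * sqrt(3) / 2              # row spacing within a layer
  kr <- floor((lo[3] - anchor[3]) / dz):ceiling((hi[3] - anchor[3]) / dz)
  jr <- floor((lo[2] - anchor[2] - a) / ry):ceiling((hi[2] - anchor[2] + a) / ry)
  out <- vector("list", length(kr))
  for (qi in seq_along(kr)) {
    k <- kr[qi]
    bshift <- if (k %% 2 == 0) c(0, 0) else c(a / 2, a / (2 * sqrt(3)))
    z <- anchor[3] + k * dz
    rows <- lapply(jr, function(j) {
      y <- anchor[2] + j * ry + bshift[2]
      xoff <- anchor[1] + (j %% 2) * (a / 2) + bshift[1]
      ir <- floor((lo[1] - xoff) / a):ceiling((hi[1] - xoff) / a)
      cbind(xoff + ir * a, y, z)
    })
    out[[qi]] <- do.call(rbind, rows)
  }
  m <- do.call(rbind, out)
  m[m[, 1] >= lo[1] & m[, 1] <= hi[1] &
    m[, 2] >= lo[2] & m[, 2] <= hi[2] &
    m[, 3] >= lo[3] & m[, 3] <= hi[3], , drop = FALSE]
}

# For each row of `sites`, is any row of `pts` within `cutoff`?
min_dist_within <- function(sites, pts, cutoff) {
  n <- nrow(sites)
  keep <- logical(n)
  c2 <- cutoff^2
  block <- max(1, floor(2e6 / max(nrow(pts), 1)))
  px <- pts[, 1]; py <- pts[, 2]; pz <- pts[, 3]
  for (s in seq(1, n, by = block)) {
    e <- min(n, s + block - 1)
    d2 <- outer(sites[s:e, 1], px, "-")^2 +
      outer(sites[s:e, 2], py, "-")^2 +
      outer(sites[s:e, 3], pz, "-")^2
    keep[s:e] <- matrixStats_rowMins(d2) <= c2
  }
  keep
}

matrixStats_rowMins <- function(m) do.call(pmin, as.data.frame(m))

#' @export
print.bead_model <- function(x, ...) {
  cat(sprintf("bead_model: %d beads, radius %.3g A (HCP lattice)\n",
              nrow(x), attr(x, "bead_radius")))
  invisible(x)
}

#' Convert a bead model to an atomic model
#'
#' Bead centers become pseudo-atoms; the bead radius is written to the
#' occupancy field, following the SAXS bead-model convention.
#'
#' @param beads a `bead_model`.
#' @return An [atomic_model].
#' @export
as_atomic_model <- function(beads) {
  stopifnot(inherits(beads, "bead_model"))
  atomic_model(beads$x, beads$y, beads$z, elety = "CA", resid = "BEA",
               chain = "A", o = attr(beads, "bead_radius"), b = 0)
}

#' Rasterize a bead model into a density map
#'
#' Delegates to [pdb2vol()] on the bead centers. Two presets reflect common
#' use: `"docking"` convolves with a hard-sphere kernel of the bead radius
#' (densely packed spheres, for correlation docking); `"envelope"` uses a
#' Gaussian whose half-maximum radius equals the bead radius, whose
#' half-maximum isosurface renders a smooth molecular envelope.
#'
#' @param beads a `bead_model`.
#' @param width voxel spacing in Angstrom.
#' @param preset `"docking"` or `"envelope"`; ignored when `kernel` given.
#' @param kernel optional explicit [kernels] object.
#' @return A [volume_map].
#' @export
beads2vol <- function(beads, width, preset = c("docking", "envelope"),
                      kernel = NULL) {
  stopifnot(inherits(beads, "bead_model"))
  r <- attr(beads, "bead_radius")
  if (is.null(kernel)) {
    preset <- match.arg(preset)
    kernel <- switch(preset,
      docking = hard_sphere_kernel(r),
      # half-max of exp(-3 r^2 / (2 s^2)) at r = s * sqrt(2 log(2) / 3)
      envelope = gaussian_kernel(sigma = r * sqrt(3 / (2 * log(2)))))
  }
  pdb2vol(as_atomic_model(beads), width = width, kernel = kernel)
}

#' Density threshold enclosing a given molecular volume
#'
#' The surface isolevel for rendering a low-resolution map is convention,
#' not physics: it is chosen so the enclosed volume is 120--150% of the
#' molecular volume (resolution lowering erodes convex and fills concave
#' features, so more than 100% is needed to keep the structure inside).
#' Resolved by sorting voxel values; the nearest achievable volume on the
#' voxel grid is used.
#'
#' @param map a [volume_map].
#' @param molecular_volume molecular volume in cubic Angstrom.
#' @param fraction enclosed-volume fraction, conventionally in `[1.2, 1.5]`.
#' @return The density threshold (scalar).
#' @export
recommended_isolevel <- function(map, molecular_volume, fraction = 1.35) {
  stopifnot(inherits(map, "volume_map"))
  if (molecular_volume <= 0) stop("molecular_volume must be positive")
  target <- fraction * molecular_volume
  k <- max(1, round(target / map$width^3))
  v <- as.vector(map$data)
  npos <- sum(v > 0)
  if (k > npos)
    stop("requested volume ", signif(target, 5), " A^3 (", k,
         " voxels) exceeds the map's positive-density volume (", npos,
         " voxels)")
  sort(v, decreasing = TRUE)[k]
}
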