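#' Cross-correlation of two density maps
#'
#' The Situs-convention cross-correlation coefficient,
#' `CC = sum(a * b) / (||a|| * ||b||)`, computed over the common lattice.
#' Unlike the Pearson coefficient, the map averages are **not** subtracted:
#' the calculated density has the physical meaning of a positive mass
#' distribution, so for two nonnegative maps `CC` lies in `[0, 1]`. For a
#' fixed probe (constant norm), maximizing this CC also maximizes the
#' Pearson coefficient.
#'
#' @param map_a,map_b [volume_map]s on the same lattice.
#' @return Scalar score in `[-1, 1]`; 0 (with a warning) if either map has
#'   zero norm.
#' @export
cc <- function(map_a, map_b) {
  stop_lattice_mismatch(map_a, map_b)
  a <- as.vector(map_a$data); b <- as.vector(map_b$data)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    warning("zero-norm map: cross-correlation undefined, returning 0")
    return(0)
  }
  sum(a * b) / (na * nb)
}

#' Discrete Laplacian contour filter
#'
#' The 6-neighbor finite-difference Laplacian,
#' `(sum of 6 neighbors - 6 * center) / width^2`, which emphasizes density
#' contours and extends correlation docking to lower resolution. Values
#' outside the map are treated as zero.
#'
#' With `mask_edges`, output voxels on the map boundary, voxels whose
#' 6-neighborhood contains a zero-density voxel, and zero-density voxels
#' themselves are set to zero. This suppresses the singular shells the
#' Laplacian produces at hard density edges left by thresholding or
#' segmentation.
#'
#' @param map a [volume_map] with at least 3 voxels per axis.
#' @param mask_edges suppress edge singularities (see Details).
#' @return A [volume_map] of the filtered density.
#' @export
laplacian_filter <- function(map, mask_edges = FALSE) {
  stopifnot(inherits(map, "volume_map"))
  d <- map$dims
  if (any(d < 3)) stop("map too small for the Laplacian stencil (need >= 3 ",
                       "voxels per axis)")
  x <- map$data
  nb_sum <- shift3(x, 1, 1) + shift3(x, 1, -1) +
    shift3(x, 2, 1) + shift3(x, 2, -1) +
    shift3(x, 3, 1) + shift3(x, 3, -1)
  out <- (nb_sum - 6 * x) / map$width^2
  if (mask_edges) {
    zero <- x == 0
    nbz <- shift3(zero, 1, 1, fill = TRUE) | shift3(zero, 1, -1, fill = TRUE) |
      shift3(zero, 2, 1, fill = TRUE) | shift3(zero, 2, -1, fill = TRUE) |
      shift3(zero, 3, 1, fill = TRUE) | shift3(zero, 3, -1, fill = TRUE)
    mask <- zero | nbz
    mask[c(1, d[1]), , ] <- TRUE
    mask[, c(1, d[2]), ] <- TRUE
    mask[, , c(1, d[3])] <- TRUE
    out[mask] <- 0
  }
  volume_map(out, width = map$width, origin = map$origin)
}

# Shift a 3D array by one voxel along an axis so that
# shift3(x, a, +1)[i] == x[i + 1] along axis a; vacated cells get `fill`.
shift3 <- function(x, axis, by, fill = 0) {
  d <- dim(x)
  out <- array(fill, dim = d)
  n <- d[axis]
  lo <- 1:(n - 1); hi <- 2:n
  if (axis == 1) {
    if (by > 0) out[lo, , ] <- x[hi, , ] else out[hi, , ] <- x[lo, , ]
  } else if (axis == 2) {
    if (by > 0) out[, lo, ] <- x[, hi, ] else out[, hi, ] <- x[, lo, ]
  } else {
    if (by > 0) out[, , lo] <- x[, , hi] else out[, , hi] <- x[, , lo]
  }
  out
}

#' FFT translational correlation scan
#'
#' Computes the cross-correlation score for every integer-voxel translation
#' of a probe map relative to a target map, via the Fourier correlation
#' theorem with zero padding (linear, not circular, correlation). The
#' normalization follows the Situs CC: the probe norm is taken over its own
#' support (constant across translations) and the target norm over the full
#' volume, so the field equals `cc` applied to the zero-embedded probe at
#' each offset.
#'
#' @param target,probe [volume_map]s with equal voxel width.
#' @return A list of class `scan_result`: `scores` (3D array over all
#'   offsets), `offsets` (per-axis integer translations, in voxels, of the
#'   probe's first voxel relative to the target's first voxel), and `best`
#'   (list with `score`, `offset`, and `shift` in Angstrom).
#' @export
fft_translation_scan <- function(target, probe) {
  stopifnot(inherits(target, "volume_map"), inherits(probe, "volume_map"))
  if (abs(target$width - probe$width) > 1e-6 * target$width)
    stop("probe width ", probe$width, " does not match target width ",
         target$width)
  tn <- sqrt(sum(target$data^2))
  pn <- sqrt(sum(probe$data^2))
  if (pn == 0) {
    warning("all-zero probe: scan field is identically zero")
  }
  dt <- target$dims; dp <- probe$dims
  full <- dt + dp - 1L
  pad <- vapply(full, function(n) stats::nextn(n, c(2, 3, 5)), 1)
  ta <- array(0, pad); ta[1:dt[1], 1:dt[2], 1:dt[3]] <- target$data
  pa <- array(0, pad); pa[1:dp[1], 1:dp[2], 1:dp[3]] <- probe$data
  # correlation: IFFT( FFT(T) * conj(FFT(P)) ) gives sum T(x+t) P(x) at t >= 0;
  # negative lags wrap to the top end of each axis.
  corr <- Re(stats::fft(stats::fft(ta) * Conj(stats::fft(pa)),
                        inverse = TRUE)) / prod(pad)
  offsets <- lapply(1:3, function(a) (-(dp[a] - 1L)):(dt[a] - 1L))
  sc <- array(0, dim = full)
  idx <- lapply(1:3, function(a) (offsets[[a]] %% pad[a]) + 1L)
  sc[] <- corr[idx[[1]], idx[[2]], idx[[3]]]
  denom <- tn * pn
  sc <- if (denom > 0) sc / denom else sc * 0
  best_i <- arrayInd(which.max(sc), dim(sc))
  best_off <- c(offsets[[1]][best_i[1]], offsets[[2]][best_i[2]],
                offsets[[3]][best_i[3]])
  structure(list(
    scores = sc, offsets = offsets,
    best = list(score = max(sc), offset = best_off,
                shift = target$origin + best_off * target$width - probe$origin)),
    class = "scan_result")
}
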