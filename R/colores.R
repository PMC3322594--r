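#' Exhaustive rigid-body search of a probe structure in a target map
#'
#' For every orientation on a homogeneously distributed Euler-angle grid,
#' the probe structure is rotated about its centroid, rasterized with the
#' same kernel and voxel width as the target's nominal resolution, and
#' scanned over all integer-voxel translations with the FFT correlation
#' theorem. The per-orientation best translations are merged into a ranked
#' pose list, with a minimal distance-based pruning of near-duplicate peaks.
#'
#' The Euler grid uses the z-y-z intrinsic convention with uniform steps in
#' `phi` and `psi` and equal-area sampling in `theta` (`cos theta` uniform),
#' so orientations are approximately homogeneous on SO(3); at the poles
#' (`theta = 0, 180`), where only `phi + psi` matters, degenerate duplicates
#' are removed.
#'
#' The optional Laplacian filter (applied to both target -- with edge
#' masking -- and probe) emphasizes shape contours and extends the viable
#' resolution range of the correlation to roughly 30 A.
#'
#' @param target a [volume_map].
#' @param probe an [atomic_model].
#' @param res nominal Situs resolution (`r_s`, Angstrom) used to rasterize
#'   the probe with a Gaussian kernel.
#' @param angular_step Euler grid step in degrees (5--90).
#' @param laplacian use Laplacian contour scoring.
#' @param n_best number of poses to keep after pruning.
#' @param prune_dist centroid separation (Angstrom) below which a weaker
#'   pose is considered a duplicate peak; default `2 * width`.
#' @param kernel override the probe rasterization kernel.
#' @return A `pose_list`: data frame of ranked poses with Euler angles
#'   (degrees), translation `tx,ty,tz` (Angstrom, applied after rotating the
#'   probe about its centroid), centroid position `cx,cy,cz`, and `score`;
#'   sorted by descending score with deterministic lexicographic tie-break.
#' @seealso [fft_translation_scan()], [collage_refine()]
#' @export
colores_search <- function(target, probe, res, angular_step = 30,
                           laplacian = FALSE, n_best = 20, prune_dist = NULL,
                           kernel = NULL) {
  stopifnot(inherits(target, "volume_map"), inherits(probe, "atomic_model"))
  if (nrow(probe) == 0) stop("empty probe")
  if (angular_step < 5 || angular_step > 90)
    stop("angular_step must be in [5, 90] degrees")
  if (is.null(kernel)) kernel <- gaussian_kernel(resolution = res)
  if (is.null(prune_dist)) prune_dist <- 2 * target$width
  tgt <- if (laplacian) laplacian_filter(target, mask_edges = TRUE) else target
  ext <- apply(coords(probe), 2, function(v) diff(range(v)))
  if (any(ext > target$dims * target$width))
    stop("probe footprint exceeds the target map extent")
  grid <- euler_grid(angular_step)
  cen <- centroid(probe)
  # fixed probe lattice (a cube holding every rotation) so the padded
  # target FFT can be computed once and reused for all orientations
  w <- target$width
  rad <- max(sqrt(rowSums(sweep(coords(probe), 2, cen)^2)))
  half <- ceiling((rad + kernel$support) / w) + 1L
  side <- 2L * half + 1L
  p_origin <- cen - half * w
  p_dims <- rep(side, 3L)
  dt <- target$dims
  full <- dt + p_dims - 1L
  pad <- vapply(full, function(n) stats::nextn(n, c(2, 3, 5)), 1)
  ta <- array(0, pad)
  ta[1:dt[1], 1:dt[2], 1:dt[3]] <- tgt$data
  ta_fft <- stats::fft(ta)
  tn <- sqrt(sum(tgt$data^2))
  offsets <- lapply(1:3, function(a) (-(p_dims[a] - 1L)):(dt[a] - 1L))
  idx <- lapply(1:3, function(a) (offsets[[a]] %% pad[a]) + 1L)
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    R <- euler_to_matrix(grid$phi[g], grid$theta[g], grid$psi[g])
    rot <- apply_transform(probe, R, t = c(0, 0, 0), center = cen)
    pm <- pdb2vol(rot, width = w, kernel = kernel,
                  lattice = list(origin = p_origin, dims = p_dims))
    if (laplacian) pm <- laplacian_filter(pm)
    pn <- sqrt(sum(pm$data^2))
    pa <- array(0, pad)
    pa[1:p_dims[1], 1:p_dims[2], 1:p_dims[3]] <- pm$data
    corr <- Re(stats::fft(ta_fft * Conj(stats::fft(pa)),
                          inverse = TRUE)) / prod(pad)
    sc <- corr[idx[[1]], idx[[2]], idx[[3]]] / (tn * pn)
    bi <- arrayInd(which.max(sc), full)
    off <- c(offsets[[1]][bi[1]], offsets[[2]][bi[2]], offsets[[3]][bi[3]])
    rows[[g]] <- data.frame(
      phi = grid$phi[g], theta = grid$theta[g], psi = grid$psi[g],
      tx = target$origin[1] + off[1] * w - p_origin[1],
      ty = target$origin[2] + off[2] * w - p_origin[2],
      tz = target$origin[3] + off[3] * w - p_origin[3],
      score = max(sc))
  }
  poses <- do.call(rbind, rows)
  poses$cx <- cen[1] + poses$tx
  poses$cy <- cen[2] + poses$ty
  poses$cz <- cen[3] + poses$tz
  poses <- poses[order(-poses$score, poses$tx, poses$ty, poses$tz,
                       poses$phi, poses$theta, poses$psi), ]
  keep <- logical(nrow(poses))
  kept_c <- matrix(numeric(0), ncol = 3)
  for (i in seq_len(nrow(poses))) {
    p <- c(poses$cx[i], poses$cy[i], poses$cz[i])
    if (nrow(kept_c) == 0 ||
        min(sqrt(rowSums(sweep(kept_c, 2, p)^2))) >= prune_dist) {
      keep[i] <- TRUE
      kept_c <- rbind(kept_c, p)
    }
    if (sum(keep) >= n_best) break
  }
  out <- poses[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "center") <- cen
  attr(out, "angular_step") <- angular_step
  class(out) <- c("pose_list", "data.frame")
  out
}

# Homogeneous Euler grid: uniform phi/psi, equal-area theta, poles deduped.
euler_grid <- function(step) {
  phi <- seq(0, 360 - step, by = step)
  psi <- seq(0, 360 - step, by = step)
  nt <- max(2L, round(180 / step) + 1L)
  theta <- acos(seq(1, -1, length.out = nt)) * 180 / pi
  g <- expand.grid(phi = phi, theta = theta, psi = psi)
  pole <- g$theta < 1e-9 | g$theta > 180 - 1e-9
  g <- g[!pole | g$psi == 0, ]
  rownames(g) <- NULL
  g
}

#' Materialize a pose from a pose list
#'
#' @param probe the probe [atomic_model] given to [colores_search()].
#' @param poses a `pose_list`.
#' @param i pose rank (row) to apply.
#' @return The transformed [atomic_model].
#' @export
apply_pose <- function(probe, poses, i = 1) {
  stopifnot(inherits(poses, "pose_list"), i >= 1, i <= nrow(poses))
  R <- euler_to_matrix(poses$phi[i], poses$theta[i], poses$psi[i])
  apply_transform(probe, R, t = c(poses$tx[i], poses$ty[i], poses$tz[i]),
                  center = attr(poses, "center"))
}
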