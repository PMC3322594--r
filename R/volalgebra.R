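#' Voxel-wise volume algebra
#'
#' Simple algebraic operations on registered maps: summation/averaging
#' (`volaver`), difference (`voldiff`), multiplication/masking (`volmult`),
#' and affine density matching (`volhist_match`). All require the inputs to
#' share one lattice (width, dims, origin) exactly; use [resample_to()] for
#' deliberate registration.
#'
#' @param maps list of [volume_map]s on one lattice.
#' @param mode `"average"` (default) or `"sum"`.
#' @return A [volume_map].
#' @name volalgebra
NULL

#' @rdname volalgebra
#' @export
volaver <- function(maps, mode = c("average", "sum")) {
  mode <- match.arg(mode)
  if (length(maps) == 0) stop("empty map list")
  for (m in maps) stop_lattice_mismatch(maps[[1]], m)
  acc <- Reduce(`+`, lapply(maps, `[[`, "data"))
  if (mode == "average") acc <- acc / length(maps)
  volume_map(acc, width = maps[[1]]$width, origin = maps[[1]]$origin)
}

#' @rdname volalgebra
#' @param a,b [volume_map]s on one lattice.
#' @export
voldiff <- function(a, b) {
  stop_lattice_mismatch(a, b)
  volume_map(a$data - b$data, width = a$width, origin = a$origin)
}

#' @rdname volalgebra
#' @param binary if `TRUE`, require `b` to contain only 0/1 (a mask).
#' @export
volmult <- function(a, b, binary = FALSE) {
  stop_lattice_mismatch(a, b)
  if (binary && !all(b$data %in% c(0, 1)))
    stop("mask is not binary (values other than 0/1 present)")
  volume_map(a$data * b$data, width = a$width, origin = a$origin)
}

#' @rdname volalgebra
#' @param source,reference maps for affine density matching: finds
#'   `alpha * source + beta` closest to `reference` in least squares.
#' @return `volhist_match`: the transformed source map, with attributes
#'   `alpha` and `beta`.
#' @export
volhist_match <- function(source, reference) {
  stop_lattice_mismatch(source, reference)
  s <- as.vector(source$data); r <- as.vector(reference$data)
  vs <- stats::var(s)
  if (vs == 0) stop("zero-variance source map: affine match is degenerate")
  alpha <- stats::cov(s, r) / vs
  beta <- mean(r) - alpha * mean(s)
  if (alpha <= 0)
    warning("least-squares density match gives non-positive gain alpha = ",
            signif(alpha, 4))
  out <- volume_map(alpha * source$data + beta, width = source$width,
                    origin = source$origin)
  attr(out, "alpha") <- alpha
  attr(out, "beta") <- beta
  out
}

#' Crop or pad a map
#'
#' Resizes the lattice by removing (positive values) or adding (negative
#' values) voxels on the low and high side of each axis. The origin shifts
#' by `width * lo_voxels`; new voxels are set to `fill`.
#'
#' @param map a [volume_map].
#' @param lo_voxels,hi_voxels integer length-3: voxels to remove (positive)
#'   or add (negative) at the low/high end of each axis.
#' @param fill value for newly created voxels.
#' @return A [volume_map].
#' @export
crop_pad <- function(map, lo_voxels = c(0, 0, 0), hi_voxels = c(0, 0, 0),
                     fill = 0) {
  stopifnot(inherits(map, "volume_map"))
  lo <- as.integer(round(lo_voxels)); hi <- as.integer(round(hi_voxels))
  nd <- map$dims - lo - hi
  if (any(nd < 1)) stop("crop removes everything: resulting dims ",
                        paste(nd, collapse = "x"))
  out <- array(fill, dim = nd)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    s0 <- max(1, 1 + lo[a]); s1 <- min(map$dims[a], map$dims[a] - hi[a])
    if (s0 > s1) { src[[a]] <- integer(0); dst[[a]] <- integer(0) }
    else { src[[a]] <- s0:s1; dst[[a]] <- (s0:s1) - lo[a] }
  }
  if (all(lengths(src) > 0))
    out[dst[[1]], dst[[2]], dst[[3]]] <- map$data[src[[1]], src[[2]], src[[3]]]
  volume_map(out, width = map$width, origin = map$origin + map$width * lo)
}

#' Threshold a map
#'
#' Voxels below `level` are set to zero; voxels at or above it are kept.
#'
#' @param map a [volume_map].
#' @param level density level.
#' @return A [volume_map].
#' @export
threshold_map <- function(map, level) {
  stopifnot(inherits(map, "volume_map"))
  d <- map$data
  d[d < level] <- 0
  volume_map(d, width = map$width, origin = map$origin)
}

#' 2D image on a square lattice
#'
#' The 2D restriction of [volume_map]: used for projections and slices.
#'
#' @param data numeric matrix.
#' @param width pixel spacing in Angstrom.
#' @param origin length-2 physical coordinate of the first pixel.
#' @return Object of class `image2d`.
#' @export
image2d <- function(data, width, origin = c(0, 0)) {
  stopifnot(is.matrix(data), width > 0, length(origin) == 2)
  structure(list(width = as.numeric(width), origin = as.numeric(origin),
                 dims = dim(data), data = data), class = "image2d")
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("image2d: %d x %d pixels, width %.4g A\n",
              x$dims[1], x$dims[2], x$width))
  invisible(x)
}

#' Difference of two 2D images
#' @param a,b `image2d` objects on one lattice.
#' @return An `image2d`.
#' @export
voldiff2d <- function(a, b) {
  stopifnot(inherits(a, "image2d"), inherits(b, "image2d"),
            all(a$dims == b$dims), abs(a$width - b$width) < 1e-9)
  image2d(a$data - b$data, width = a$width, origin = a$origin)
}

#' Project or slice a map along an axis
#'
#' `project_map` integrates along the chosen axis (sum times `width`, the
#' Riemann approximation of the line integral); `slice_map` extracts one
#' plane as-is. Because projection is linear, the projection of a
#' difference map equals the difference of the projections.
#'
#' @param map a [volume_map].
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param index 1-based plane index for `slice_map`.
#' @return An [image2d] over the two remaining axes (in x,y,z order).
#' @export
project_map <- function(map, axis = c("z", "x", "y")) {
  axis <- match.arg(axis)
  ax <- match(axis, c("x", "y", "z"))
  keep <- setdiff(1:3, ax)
  dat <- apply(map$data, keep, sum) * map$width
  image2d(dat, width = map$width, origin = map$origin[keep])
}

#' @rdname project_map
#' @export
slice_map <- function(map, axis = c("z", "x", "y"), index) {
  axis <- match.arg(axis)
  ax <- match(axis, c("x", "y", "z"))
  if (index < 1 || index > map$dims[ax]) stop("slice index out of range")
  keep <- setdiff(1:3, ax)
  idx <- list(TRUE, TRUE, TRUE)
  idx[[ax]] <- index
  dat <- do.call(`[`, c(list(map$data), idx, drop = FALSE))
  dat <- array(dat, dim = map$dims[keep])
  image2d(dat, width = map$width, origin = map$origin[keep])
}

#' Write a 2D image as a plain-text matrix
#'
#' One row per line, whitespace-separated, with a two-line comment header
#' recording width and origin.
#'
#' @param img an [image2d].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_image2d <- function(img, path) {
  stopifnot(inherits(img, "image2d"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# image2d width %s origin %s %s", fmt_g6(img$width),
                     fmt_g6(img$origin[1]), fmt_g6(img$origin[2])), con)
  writeLines(sprintf("# dims %d %d", img$dims[1], img$dims[2]), con)
  utils::write.table(t(img$data), con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Connected-component segmentation of super-threshold density
#'
#' Labels 6-connected components of `{density >= level}`; labels are
#' assigned by descending total component density (label 1 is the densest
#' region).
#'
#' @param map a [volume_map].
#' @param level density threshold.
#' @return A list with `labels` (integer array, 0 = below threshold) and
#'   `n` (number of components).
#' @export
segment_connected <- function(map, level) {
  stopifnot(inherits(map, "volume_map"))
  d <- map$dims
  sel <- map$data >= level
  lab <- array(0L, dim = d)
  nxt <- 0L
  idx_all <- which(sel)
  if (length(idx_all) == 0) return(list(labels = lab, n = 0L))
  strides <- c(1L, d[1], d[1] * d[2])
  for (start in idx_all) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      ijk <- arrayInd(cur, d)
      for (a in 1:3) for (s in c(-1L, 1L)) {
        ok <- ijk[, a] + s >= 1L & ijk[, a] + s <= d[a]
        if (!any(ok)) next
        nb <- cur[ok] + s * strides[a]
        nb <- nb[sel[nb] & lab[nb] == 0L]
        if (length(nb)) {
          nb <- unique(nb)
          lab[nb] <- nxt
          queue <- c(queue, nb)
        }
      }
    }
  }
  # relabel by descending total density
  tot <- vapply(seq_len(nxt), function(l) sum(map$data[lab == l]), 0)
  ord <- order(tot, decreasing = TRUE)
  remap <- integer(nxt)
  remap[ord] <- seq_len(nxt)
  pos <- lab != 0L
  lab[pos] <- remap[lab[pos]]
  list(labels = lab, n = nxt)
}

#' Trilinear resampling of a map onto another lattice
#'
#' Samples `map` at the voxel centers of the target lattice by trilinear
#' interpolation; positions outside the source map get zero. This is the
#' deliberate-registration companion to the strict lattice-identity policy
#' of the voxel-wise operations.
#'
#' @param map source [volume_map].
#' @param lattice a [volume_map] to copy the lattice from, or a list with
#'   `width`, `origin`, `dims`.
#' @return A [volume_map] on the target lattice.
#' @export
resample_to <- function(map, lattice) {
  stopifnot(inherits(map, "volume_map"))
  w <- lattice$width; org <- lattice$origin; d <- as.integer(lattice$dims)
  g <- expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1), k = 0:(d[3] - 1))
  pos <- sweep(as.matrix(g) * w, 2, org, "+")
  f <- sweep(pos, 2, map$origin) / map$width
  i0 <- floor(f); fr <- f - i0
  acc <- numeric(nrow(f))
  for (corner in 0:7) {
    dx <- corner %% 2; dy <- (corner %/% 2) %% 2; dz <- corner %/% 4
    ii <- i0[, 1] + dx; jj <- i0[, 2] + dy; kk <- i0[, 3] + dz
    ok <- ii >= 0 & ii < map$dims[1] & jj >= 0 & jj < map$dims[2] &
      kk >= 0 & kk < map$dims[3]
    wt <- (dx * fr[, 1] + (1 - dx) * (1 - fr[, 1])) *
      (dy * fr[, 2] + (1 - dy) * (1 - fr[, 2])) *
      (dz * fr[, 3] + (1 - dz) * (1 - fr[, 3]))
    idx <- 1 + ii[ok] + map$dims[1] * (jj[ok] + map$dims[2] * kk[ok])
    acc[ok] <- acc[ok] + wt[ok] * as.vector(map$data)[idx]
  }
  volume_map(acc, width = w, origin = org, dims = d)
}
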