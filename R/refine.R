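#' Simultaneous multi-fragment off-lattice refinement
#'
#' Maximizes the Situs cross-correlation of the *joint* calculated density
#' of several rigid fragments against a target map, over all `6 K` pose
#' parameters at once (three translations in Angstrom and a three-component
#' rotation vector in degrees per fragment, composed onto the current
#' orientation about the fragment centroid; the rotation-vector form keeps
#' all three rotational degrees of freedom independent near the identity,
#' where z-y-z Euler increments are gimbal-degenerate). Because the fragments are
#' rasterized into one calculated map and normalized jointly, overlapping
#' fragments inflate the norm without gaining overlap with the target, so
#' steric clashes are penalized by the score itself.
#'
#' Optimization is by a derivative-free Powell direction-set method built on
#' successive one-dimensional line maximizations; a line move is accepted
#' only if it improves the score, so the score trace is monotone
#' non-decreasing. `max_steps = 1` performs a single direction-set pass --
#' the building block of the symmetry-constrained refinement loop.
#'
#' @param target a [volume_map].
#' @param fragments a single [atomic_model] or a list of them, at their
#'   starting poses.
#' @param res nominal Situs resolution (Angstrom) for the Gaussian
#'   rasterization kernel.
#' @param laplacian score with the Laplacian contour filter.
#' @param max_steps maximum number of Powell direction-set passes.
#' @param frozen logical vector: fragments to hold fixed.
#' @param line_halfwidth half-width of each line search, in Angstrom
#'   (translations) / degrees (rotations).
#' @param tol convergence: stop when a full pass improves the score by less
#'   than `tol`.
#' @param kernel override the rasterization kernel.
#' @return A `fragment_set` list: `models` (refined fragments),
#'   `transforms` (data frame of per-fragment accumulated translation and
#'   rotation parameters), `trace` (score after the start and after each
#'   pass; monotone non-decreasing), and `score`.
#' @seealso [colores_search()], [symmetry_constrained_refine()]
#' @export
collage_refine <- function(target, fragments, res, laplacian = FALSE,
                           max_steps = 50, frozen = NULL,
                           line_halfwidth = 8, tol = 1e-6, kernel = NULL) {
  stopifnot(inherits(target, "volume_map"))
  if (inherits(fragments, "atomic_model")) fragments <- list(fragments)
  if (length(fragments) == 0) stop("empty fragment set")
  for (f in fragments) stopifnot(inherits(f, "atomic_model"))
  if (is.null(frozen)) frozen <- rep(FALSE, length(fragments))
  if (is.null(kernel)) kernel <- gaussian_kernel(resolution = res)
  K <- length(fragments)
  cens <- lapply(fragments, centroid)
  lat <- list(origin = target$origin, dims = target$dims)
  kern <- rasterize_kernel(kernel, target$width)
  kfft <- kernel_fft(kern, target$dims)
  tgt <- if (laplacian) laplacian_filter(target, mask_edges = TRUE) else target
  tvec <- as.vector(tgt$data)
  tnorm <- sqrt(sum(tvec^2))
  xyz0 <- lapply(fragments, coords)

  calc_cc <- function(par) {
    lat_sum <- array(0, dim = target$dims)
    for (k in seq_len(K)) {
      p <- par[(6 * (k - 1) + 1):(6 * k)]
      R <- rotvec_matrix(p[4:6])
      pos <- apply_transform(xyz0[[k]], R, t = p[1:3], center = cens[[k]])
      lat_sum <- lat_sum + trilinear_project(pos, rep(1, nrow(pos)),
                                             target$origin, target$width,
                                             target$dims)
    }
    calc <- convolve_lattice(lat_sum, kern, kern_fft = kfft)
    if (laplacian)
      calc <- laplacian_filter(volume_map(calc, target$width,
                                          target$origin))$data
    cn <- sqrt(sum(calc^2))
    if (!is.finite(cn) || cn == 0 || tnorm == 0) return(NA_real_)
    sum(calc * tvec) / (cn * tnorm)
  }

  par0 <- rep(0, 6 * K)
  free <- rep(!frozen, each = 6)
  s0 <- calc_cc(par0)
  if (!is.finite(s0)) stop("non-finite score at the starting poses ",
                           "(degenerate rasterization)")
  opt <- powell_maximize(calc_cc, par0, free = free,
                         halfwidth = line_halfwidth,
                         max_cycles = max_steps, tol = tol)
  par <- opt$par
  models <- vector("list", K)
  tr <- data.frame(fragment = seq_len(K), tx = 0, ty = 0, tz = 0,
                   rx = 0, ry = 0, rz = 0)
  for (k in seq_len(K)) {
    p <- par[(6 * (k - 1) + 1):(6 * k)]
    R <- rotvec_matrix(p[4:6])
    models[[k]] <- apply_transform(fragments[[k]], R, t = p[1:3],
                                   center = cens[[k]])
    tr[k, 2:7] <- p
  }
  structure(list(models = models, transforms = tr,
                 trace = opt$trace, score = opt$value),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("fragment_set: %d fragment(s), CC %.6f after %d pass(es)\n",
              length(x$models), x$score, length(x$trace) - 1))
  invisible(x)
}

# Powell direction-set maximization with improvement-only acceptance.
# Directions start as the coordinate axes; after each cycle the direction of
# total displacement replaces the direction of largest single gain. Line
# searches use stats::optimize on [-halfwidth, halfwidth] around the current
# point and are accepted only when they improve the value, which makes the
# returned trace monotone non-decreasing.
powell_maximize <- function(f, par0, free = NULL, halfwidth = 8,
                            max_cycles = 50, tol = 1e-6, line_tol = 1e-3) {
  n <- length(par0)
  if (is.null(free)) free <- rep(TRUE, n)
  dirs <- diag(n)[, free, drop = FALSE]
  par <- par0
  val <- f(par)
  trace <- val
  for (cycle in seq_len(max_cycles)) {
    par_start <- par
    val_start <- val
    gain_best <- 0
    i_best <- 0L
    for (i in seq_len(ncol(dirs))) {
      d <- dirs[, i]
      g <- function(a) {
        v <- f(par + a * d)
        if (is.finite(v)) v else -Inf
      }
      o <- stats::optimize(g, interval = c(-halfwidth, halfwidth),
                           maximum = TRUE, tol = line_tol)
      if (is.finite(o$objective) && o$objective > val) {
        if (o$objective - val > gain_best) {
          gain_best <- o$objective - val
          i_best <- i
        }
        par <- par + o$maximum * d
        val <- o$objective
      }
    }
    disp <- par - par_start
    if (i_best > 0L && sqrt(sum(disp^2)) > 1e-12) {
      d <- disp / sqrt(sum(disp^2))
      g <- function(a) {
        v <- f(par + a * d)
        if (is.finite(v)) v else -Inf
      }
      o <- stats::optimize(g, interval = c(-halfwidth, halfwidth),
                           maximum = TRUE, tol = line_tol)
      if (is.finite(o$objective) && o$objective > val) {
        par <- par + o$maximum * d
        val <- o$objective
      }
      dirs[, i_best] <- d
    }
    trace <- c(trace, val)
    if (val - val_start < tol) break
  }
  list(par = par, value = val, trace = trace)
}
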