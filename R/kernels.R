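#' Point-spread kernels for resolution lowering
#'
#' Three kernel families are supported for the real-space convolution that
#' lowers the resolution of an atomic structure:
#'
#' * **Gaussian**: `exp(-3 r^2 / (2 sigma^2))`, where `sigma` is the
#'   three-dimensional standard deviation. The Situs resolution convention
#'   sets `r_s = 2 sigma`, so `gaussian_kernel(resolution = r_s)` uses
#'   `sigma = r_s / 2`. The kernel is truncated at `r = 3 sigma`, where its
#'   amplitude has fallen to `exp(-13.5) ~ 1.4e-6`.
#' * **Triangular**: `max(0, 1 - r / radius)`.
#' * **Hard sphere**: `1` for `r <= radius`, else `0`.
#'
#' @param resolution Situs resolution `r_s` in Angstrom (Gaussian only).
#' @param sigma alternatively, the Gaussian sigma directly.
#' @param radius kernel radius in Angstrom (triangular / hard sphere).
#' @return A `density_kernel` object with fields `family`, `fun(r)` and
#'   `support` (truncation radius in Angstrom).
#' @examples
#' k <- gaussian_kernel(resolution = 10)
#' k$fun(0)      # 1 at the center
#' k$support     # 3 * sigma = 15 A
#' @name kernels
NULL

new_kernel <- function(family, fun, support, params) {
  structure(list(family = family, fun = fun, support = support,
                 params = params), class = "density_kernel")
}

#' @rdname kernels
#' @export
gaussian_kernel <- function(resolution = NULL, sigma = NULL) {
  if (is.null(sigma)) {
    if (is.null(resolution)) stop("give resolution (r_s) or sigma")
    sigma <- resolution / 2
  }
  if (sigma <= 0) stop("sigma must be positive")
  s2 <- sigma^2
  new_kernel("gaussian",
             function(r) exp(-3 * r^2 / (2 * s2)),
             support = 3 * sigma,
             params = list(sigma = sigma, resolution = 2 * sigma))
}

#' @rdname kernels
#' @export
triangular_kernel <- function(radius) {
  if (radius <= 0) stop("radius must be positive")
  new_kernel("triangular",
             function(r) pmax(0, 1 - r / radius),
             support = radius, params = list(radius = radius))
}

#' @rdname kernels
#' @export
hard_sphere_kernel <- function(radius) {
  if (radius <= 0) stop("radius must be positive")
  new_kernel("hard_sphere",
             function(r) as.numeric(r <= radius),
             support = radius, params = list(radius = radius))
}

#' @export
print.density_kernel <- function(x, ...) {
  cat(sprintf("density_kernel: %s (%s), support %.3g A\n", x$family,
              paste(names(x$params), signif(unlist(x$params), 4),
                    sep = "=", collapse = ", "),
              x$support))
  invisible(x)
}

# Sample a kernel on the voxel lattice: odd-sized cube of values
# fun(|offset| * width), zero outside the support radius.
rasterize_kernel <- function(kernel, width) {
  stopifnot(inherits(kernel, "density_kernel"), width > 0)
  K <- ceiling(kernel$support / width)
  off <- (-K):K
  g <- expand.grid(x = off, y = off, z = off)
  r <- sqrt(g$x^2 + g$y^2 + g$z^2) * width
  v <- kernel$fun(r)
  v[r > kernel$support] <- 0
  array(v, dim = c(2 * K + 1, 2 * K + 1, 2 * K + 1))
}

# FFT convolution of a lattice with a centered kernel cube, assuming the
# lattice already carries enough zero margin that circular wraparound does
# not reach any occupied voxel.
convolve_lattice <- function(lattice, kern, kern_fft = NULL) {
  d <- dim(lattice)
  if (is.null(kern_fft)) kern_fft <- kernel_fft(kern, d)
  re <- Re(stats::fft(stats::fft(lattice) * kern_fft, inverse = TRUE)) / prod(d)
  array(re, dim = d)
}

# FFT of a kernel cube embedded (wrapped) into a lattice of dims d so that
# its center sits at index (1,1,1).
kernel_fft <- function(kern, d) {
  kd <- dim(kern)
  if (any(kd > d))
    stop("kernel support (", paste(kd, collapse = "x"),
         ") exceeds lattice dims (", paste(d, collapse = "x"), ")")
  K <- (kd - 1L) %/% 2L
  emb <- array(0, dim = d)
  src <- lapply(1:3, function(a) seq_len(kd[a]))
  dst <- lapply(1:3, function(a) ((seq_len(kd[a]) - 1 - K[a]) %% d[a]) + 1)
  emb[dst[[1]], dst[[2]], dst[[3]]] <-
    kern[src[[1]], src[[2]], src[[3]]]
  stats::fft(emb)
}
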