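#' Synthetic test structures and maps
#'
#' Reproducible synthetic fixtures replace downloadable structures in all
#' tests and examples: a pseudo-atomic "monomer" blob with a deliberately
#' asymmetric shape, and simulated low-resolution maps of symmetric
#' assemblies built from it, with the planted ground-truth transforms
#' returned alongside for recovery checks.
#'
#' @param n_atoms number of pseudo-atoms.
#' @param rg target radius of gyration in Angstrom.
#' @param seed integer seed; the same seed gives an identical fixture.
#' @param center centroid position of the blob.
#' @return `make_monomer`: an [atomic_model] whose principal moments of
#'   inertia are pairwise distinct by at least 10% (no accidental
#'   self-symmetry).
#' @name fixtures
NULL

#' @rdname fixtures
#' @export
make_monomer <- function(n_atoms = 120, rg = 9, seed = 1,
                         center = c(0, 0, 0)) {
  if (n_atoms < 4) stop("need at least 4 atoms")
  set.seed(seed)
  for (attempt in 1:50) {
    # anisotropic Gaussian blob: distinct axis scales break self-symmetry
    x <- cbind(stats::rnorm(n_atoms, sd = 1.0),
               stats::rnorm(n_atoms, sd = 0.62),
               stats::rnorm(n_atoms, sd = 0.40))
    x <- sweep(x, 2, colMeans(x))
    x <- x * rg / sqrt(mean(rowSums(x^2)))
    mom <- sort(eigen(crossprod(x) / n_atoms, symmetric = TRUE)$values)
    if (mom[1] * 1.1 <= mom[2] && mom[2] * 1.1 <= mom[3]) break
  }
  x <- sweep(x, 2, center, "+")
  atomic_model(x[, 1], x[, 2], x[, 3], elety = "CA", resid = "GLY",
               chain = "A", b = 0, o = 1)
}

#' @rdname fixtures
#' @param order rotational order of the cyclic assembly.
#' @param ring_radius distance of the monomer centroid from the symmetry
#'   axis (z through the origin), Angstrom.
#' @param width voxel spacing of the simulated map, Angstrom.
#' @param res simulated Situs resolution (Gaussian kernel), Angstrom.
#' @return `make_assembly_map`: a list with `map` (the simulated
#'   [volume_map]), `master` (the monomer placed at the first protomer
#'   site), `mates` (all planted protomers), `truth` (per-protomer list of
#'   rotation `R`, translation `t` and centroid position `centroid`),
#'   `model` (the combined assembly), and `spec` (the [symmetry_spec]).
#' @export
make_assembly_map <- function(order = 6, n_atoms = 180, rg = 16,
                              ring_radius = 33, width = 3, res = 15,
                              seed = 1) {
  master <- make_monomer(n_atoms = n_atoms, rg = rg, seed = seed,
                         center = c(ring_radius, 0, 0))
  spec <- symmetry_spec("C", order = order, axis_point = c(0, 0, 0),
                        axis_dir = c(0, 0, 1))
  mates <- pdbsymm(master, spec)
  model <- combine_models(mates, chains = LETTERS[seq_along(mates)])
  map <- pdb2vol(model, width = width,
                 kernel = gaussian_kernel(resolution = res))
  truth <- lapply(mates, function(m)
    list(R = attr(m, "R"), t = attr(m, "t"), centroid = centroid(m)))
  list(map = map, master = master, mates = mates, truth = truth,
       model = model, spec = spec)
}

#' @rdname fixtures
#' @param ... passed to `make_assembly_map` (with `order = 6`).
#' @return `make_hexamer_map`: as `make_assembly_map` with `order = 6` --
#'   a simulated 15 A-resolution hexamer map by default.
#' @export
make_hexamer_map <- function(...) make_assembly_map(order = 6, ...)
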