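test_that("a lattice-aligned atom with a hard-sphere kernel conserves mass", {
  m <- atomic_model(10, 10, 10)
  vol <- pdb2vol(m, width = 2, kernel = hard_sphere_kernel(2))
  expect_equal(sum(vol$data),
               attr(vol, "total_weight") * attr(vol, "kernel_sum"),
               tolerance = 1e-9)
  expect_equal(attr(vol, "total_weight"), 1)
  # density forms a 7-voxel ball (center + 6 face neighbors at distance w)
  expect_equal(sum(vol$data > 1e-12), 7)
})

test_that("a centered Gaussian rasterization peaks at the atom and is isotropic", {
  m <- atomic_model(0, 0, 0)
  vol <- pdb2vol(m, width = 2, kernel = gaussian_kernel(resolution = 10))
  peak <- which(vol$data == max(vol$data), arr.ind = TRUE)[1, ]
  pos <- voxel_position(vol, matrix(peak - 1, 1))
  expect_equal(as.vector(pos), c(0, 0, 0))
  i <- peak[1]; j <- peak[2]; k <- peak[3]
  nb <- c(vol$data[i + 1, j, k], vol$data[i - 1, j, k],
          vol$data[i, j + 1, k], vol$data[i, j - 1, k],
          vol$data[i, j, k + 1], vol$data[i, j, k - 1])
  expect_equal(max(nb) - min(nb), 0, tolerance = 1e-12)
})

test_that("rasterization is linear: two atoms equal the sum of each alone", {
  a <- atomic_model(1.3, 2.1, -0.7)
  b <- atomic_model(6.2, -1.5, 3.9)
  both <- atomic_model(c(1.3, 6.2), c(2.1, -1.5), c(-0.7, 3.9))
  lat <- list(origin = c(-12, -12, -12), dims = c(16, 16, 16))
  k <- gaussian_kernel(resolution = 8)
  va <- pdb2vol(a, 2, k, lattice = lat)
  vb <- pdb2vol(b, 2, k, lattice = lat)
  vab <- pdb2vol(both, 2, k, lattice = lat)
  expect_equal(vab$data, va$data + vb$data, tolerance = 1e-10)
})

test_that("trilinear projection conserves total weight before convolution", {
  set.seed(33)
  model <- random_model(25, spread = 8)
  vol <- pdb2vol(model, width = 1.7, kernel = gaussian_kernel(resolution = 6))
  expect_equal(attr(vol, "total_weight"), 25)
  volm <- pdb2vol(model, width = 1.7, kernel = gaussian_kernel(resolution = 6),
                  mass_weighting = TRUE)
  expect_equal(sum(volm$data),
               attr(volm, "total_weight") * attr(volm, "kernel_sum"),
               tolerance = 1e-8)
})

test_that("undersampled Gaussian kernels trigger a warning", {
  m <- atomic_model(0, 0, 0)
  expect_warning(pdb2vol(m, width = 3, kernel = gaussian_kernel(resolution = 4)),
                 "undersampled")
  expect_error(pdb2vol(m, width = -1), "positive")
})

test_that("vol2pdb encodes positive voxels as occupancy-weighted atoms", {
  d <- array(0, c(3, 3, 3))
  d[1, 1, 1] <- 0.5; d[3, 2, 1] <- 1.5; d[2, 2, 2] <- -1; d[1, 3, 3] <- 2.5
  m <- volume_map(d, width = 2, origin = c(10, 0, 0))
  atoms <- vol2pdb(m, threshold = 0)
  expect_equal(nrow(atoms), 3L)
  # x-fastest ordering and voxel positions
  expect_equal(atoms$o, c(0.5, 1.5, 2.5))
  expect_equal(coords(atoms)[1, ], c(10, 0, 0), ignore_attr = TRUE)
  expect_equal(coords(atoms)[2, ], c(10 + 4, 2, 0), ignore_attr = TRUE)
  expect_error(vol2pdb(volume_map(array(-1, c(2, 2, 2)), 1)), "threshold")
})

test_that("vol2pdb then re-rasterization reproduces lattice-aligned density", {
  d <- array(0, c(5, 5, 5))
  d[2, 3, 2] <- 2; d[4, 2, 3] <- 1; d[3, 3, 3] <- 5
  m <- volume_map(d, width = 2, origin = c(0, 0, 0))
  atoms <- vol2pdb(m)
  # weight by the encoded densities, delta-like kernel on the same lattice
  back <- pdb2vol(atomic_model(atoms$x, atoms$y, atoms$z, o = atoms$o),
                  width = 2, kernel = hard_sphere_kernel(1e-6),
                  lattice = list(origin = m$origin, dims = m$dims))
  # hard-sphere of ~zero radius keeps only the center voxel (up to FFT
  # round-off dust of ~1e-16 elsewhere); scale by density
  per_atom <- back$data
  expect_equal(which(per_atom > 1e-9), which(d > 0))
  expect_equal(per_atom[per_atom > 1e-9], rep(1, 3), tolerance = 1e-9)
})

test_that("pdb2sax keeps HCP contact and reproduces single-atom anchoring", {
  one <- atomic_model(4.2, -1.1, 7.3)
  beads <- pdb2sax(one, bead_radius = 3)
  expect_equal(nrow(beads), 1L)
  expect_equal(unlist(beads[1, ]), c(4.2, -1.1, 7.3), ignore_attr = TRUE)
  mono <- make_monomer(n_atoms = 60, rg = 9, seed = 6)
  bm <- pdb2sax(mono, bead_radius = 2.5)
  expect_gt(nrow(bm), 5)
  dmat <- as.matrix(dist(cbind(bm$x, bm$y, bm$z)))
  diag(dmat) <- Inf
  expect_gte(min(dmat), 2 * 2.5 - 1e-9)      # no overlapping beads
  expect_lt(min(dmat), 2 * 2.5 + 1e-9)       # and contact is achieved
  # every bead has an atom within its radius (the keep rule)
  dd <- outer(bm$x, mono$x, "-")^2 + outer(bm$y, mono$y, "-")^2 +
    outer(bm$z, mono$z, "-")^2
  expect_true(all(apply(dd, 1, min) <= 2.5^2 + 1e-9))
})

test_that("bead count does not grow with bead radius", {
  mono <- make_monomer(n_atoms = 80, rg = 10, seed = 7)
  counts <- vapply(c(2, 3, 4, 5, 6),
                   function(r) nrow(pdb2sax(mono, bead_radius = r)), 0L)
  expect_true(all(diff(counts) <= 0))
  expect_error(pdb2sax(mono, bead_radius = -1), "positive")
})

test_that("the envelope preset yields the half-maximum radius at the bead radius", {
  one <- atomic_model(0, 0, 0)
  beads <- structure(data.frame(x = 0, y = 0, z = 0), bead_radius = 3,
                     class = c("bead_model", "data.frame"))
  env <- beads2vol(beads, width = 0.5, preset = "envelope")
  peak <- max(env$data)
  ax <- voxel_axes(env)
  j <- which.min(abs(ax$y)); k <- which.min(abs(ax$z))
  prof <- env$data[, j, k]
  # interpolate the half-maximum crossing along +x
  xs <- ax$x[xs_ok <- ax$x >= 0]
  pr <- prof[xs_ok]
  i <- max(which(pr >= peak / 2))
  r_half <- xs[i] + (pr[i] - peak / 2) / (pr[i] - pr[i + 1]) * 0.5
  expect_equal(r_half, 3, tolerance = 0.05)
  # docking preset: hard spheres conserve bead mass
  dock <- beads2vol(beads, width = 0.5, preset = "docking")
  expect_equal(sum(dock$data),
               attr(dock, "total_weight") * attr(dock, "kernel_sum"),
               tolerance = 1e-9)
})

test_that("recommended isolevels follow the sorted-volume rule", {
  m <- volume_map(1:1000, width = 1, dims = c(10, 10, 10))
  # target volume 250 A^3 -> the 250 largest voxels -> threshold value 751
  expect_equal(recommended_isolevel(m, molecular_volume = 250, fraction = 1),
               sort(1:1000, decreasing = TRUE)[250])
  t12 <- recommended_isolevel(m, 400, fraction = 1.2)
  t15 <- recommended_isolevel(m, 400, fraction = 1.5)
  expect_lte(t15, t12)
  expect_equal(recommended_isolevel(m, 1000, fraction = 1), 1)
  expect_error(recommended_isolevel(m, 2000, fraction = 1.5), "exceeds")
})
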