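test_that("the cosine-form CC matches a brute-force triple loop", {
  set.seed(40)
  for (rep in 1:10) {
    a <- random_map(c(5, 5, 5))
    b <- random_map(c(5, 5, 5))
    expect_equal(cc(a, b), cc_brute(a, b), tolerance = 1e-12)
  }
})

test_that("CC is 1 on self, scale-invariant, and in [0,1] for positive maps", {
  m <- random_map(c(6, 6, 6), seed = 41)
  expect_equal(cc(m, m), 1, tolerance = 1e-14)
  scaled <- volume_map(3.7 * m$data, m$width, m$origin)
  expect_equal(cc(m, scaled), 1, tolerance = 1e-14)
  for (rep in 1:5) {
    a <- random_map(c(5, 5, 5), positive = TRUE)
    b <- random_map(c(5, 5, 5), positive = TRUE)
    v <- cc(a, b)
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
  z <- volume_map(array(0, c(5, 5, 5)), 2)
  expect_warning(v0 <- cc(m2 <- random_map(c(5, 5, 5)), z), "zero-norm")
  expect_equal(v0, 0)
  expect_error(cc(m, random_map(c(4, 4, 4))), "lattice")
})

test_that("maximizing the cosine CC also maximizes the Pearson CC for a fixed probe", {
  # both scores integrate over the full volume V; with the probe embedded
  # in zeros its norm and mean are constant across translations, so the
  # Pearson score is a monotone function of the overlap integral and the
  # two coefficients must rank every translation identically
  target <- blob_map(c(10, 10, 10), width = 1, sigma = 2.5,
                     center = c(4, 5, 3.5))
  probe <- volume_map(target$data[3:6, 4:7, 2:5], 1)
  contained <- expand.grid(x = 0:6, y = 0:6, z = 0:6)
  cosv <- pear <- numeric(nrow(contained))
  tvec <- as.vector(target$data)
  for (r in seq_len(nrow(contained))) {
    o <- unlist(contained[r, ])
    emb <- array(0, c(10, 10, 10))
    emb[o[1] + 1:4, o[2] + 1:4, o[3] + 1:4] <- probe$data
    cosv[r] <- sum(tvec * emb) / sqrt(sum(tvec^2) * sum(emb^2))
    pear[r] <- stats::cor(tvec, as.vector(emb))
  }
  expect_equal(which.max(cosv), which.max(pear))
  # Pearson is an affine function of the overlap integral here, so it must
  # be non-decreasing along the cosine ordering (up to float noise)
  expect_true(all(diff(pear[order(cosv)]) >= -1e-9))
})

test_that("the Laplacian of simple fields follows the finite-difference form", {
  const <- volume_map(array(7, c(5, 5, 5)), width = 2)
  lap <- laplacian_filter(const)
  expect_equal(max(abs(lap$data[2:4, 2:4, 2:4])), 0)
  # quadratic ramp along x: value i^2 -> interior Laplacian 2 / width^2
  i2 <- array(rep((0:6)^2, 5 * 5), c(7, 5, 5))
  ramp <- volume_map(i2, width = 2)
  lap2 <- laplacian_filter(ramp)
  expect_equal(lap2$data[2:6, 2:4, 2:4],
               array(2 / 4, c(5, 3, 3)), tolerance = 1e-12)
  expect_error(laplacian_filter(random_map(c(2, 5, 5))), "small")
})

test_that("edge masking zeroes the shell around a thresholded blob", {
  d <- array(0, c(9, 9, 9))
  d[4:6, 4:6, 4:6] <- 1
  m <- volume_map(d, width = 1)
  lap <- laplacian_filter(m, mask_edges = TRUE)
  # voxels adjacent to the zero region (the singular shell) are suppressed
  expect_equal(max(abs(lap$data)), 0)
  unmasked <- laplacian_filter(m)
  expect_gt(max(abs(unmasked$data)), 0)
  # interior of a smooth nonzero map survives masking
  b <- blob_map(c(9, 9, 9), width = 1, sigma = 4)
  lb <- laplacian_filter(b, mask_edges = TRUE)
  expect_gt(max(abs(lb$data)), 0)
  expect_equal(max(abs(lb$data[1, , ])), 0)    # boundary always masked
})

test_that("the FFT translation scan equals a brute-force overlap loop", {
  set.seed(43)
  target <- random_map(c(8, 8, 8), width = 1, positive = TRUE)
  probe <- random_map(c(3, 3, 3), width = 1, positive = TRUE)
  sc <- fft_translation_scan(target, probe)
  tn <- sqrt(sum(target$data^2)); pn <- sqrt(sum(probe$data^2))
  for (rep in 1:25) {
    off <- c(sample(-2:7, 1), sample(-2:7, 1), sample(-2:7, 1))
    acc <- 0
    for (a in 1:3) for (b in 1:3) for (c3 in 1:3) {
      i <- a + off[1]; j <- b + off[2]; k <- c3 + off[3]
      if (all(c(i, j, k) >= 1) && all(c(i, j, k) <= 8))
        acc <- acc + target$data[i, j, k] * probe$data[a, b, c3]
    }
    idx <- vapply(1:3, function(a) match(off[a], sc$offsets[[a]]), 1L)
    expect_equal(sc$scores[idx[1], idx[2], idx[3]], acc / (tn * pn),
                 tolerance = 1e-8)
  }
})

test_that("a planted sub-block of a structured map is found at its true offset", {
  target <- blob_map(c(12, 12, 12), width = 2, sigma = 3)
  probe <- volume_map(target$data[3:10, 2:9, 4:11], 2)
  sc <- fft_translation_scan(target, probe)
  expect_equal(sc$best$offset, c(2, 1, 3))
  # probe equal to the whole target: zero offset, CC exactly 1
  sc2 <- fft_translation_scan(target, target)
  expect_equal(sc2$best$offset, c(0, 0, 0))
  expect_equal(sc2$best$score, 1, tolerance = 1e-12)
  expect_warning(fft_translation_scan(target,
    volume_map(array(0, c(3, 3, 3)), 2)), "all-zero")
  expect_error(fft_translation_scan(target, volume_map(1, 3, dims = c(1, 1, 1))),
               "width")
})

test_that("Laplacian correlation separates equal-volume cube and sphere better", {
  # equal-volume cube and ball on one lattice, smoothed identically;
  # the contour filter must sharpen the shape contrast
  d <- c(17, 17, 17)
  ax <- (0:16) - 8
  g <- expand.grid(x = ax, y = ax, z = ax)
  r <- sqrt(g$x^2 + g$y^2 + g$z^2)
  ball <- volume_map(as.numeric(r <= 5.0), 1, dims = d)           # ~523 vox
  halfside <- (4 / 3 * pi * 5^3)^(1 / 3) / 2                      # equal volume
  cube <- volume_map(as.numeric(abs(g$x) <= halfside & abs(g$y) <= halfside &
                                  abs(g$z) <= halfside), 1, dims = d)
  k <- gaussian_kernel(resolution = 4)
  kern <- minisitus:::rasterize_kernel(k, 1)
  smooth <- function(m) volume_map(minisitus:::convolve_lattice(m$data, kern),
                                   1, m$origin)
  bs <- smooth(ball); cs <- smooth(cube)
  plain <- cc(bs, cs)
  lap <- cc(laplacian_filter(bs), laplacian_filter(cs))
  expect_lt(lap, plain)   # contours disagree more than bulk volumes
  expect_gt(plain, 0.9)   # bulk correlation alone barely separates them
})
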