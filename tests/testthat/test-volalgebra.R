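test_that("voxel-wise operations match explicit loops on random maps", {
  set.seed(20)
  for (rep in 1:3) {
    a <- random_map(c(6, 6, 6), width = 1.5)
    b <- random_map(c(6, 6, 6), width = 1.5)
    expect_equal(volaver(list(a, b))$data, (a$data + b$data) / 2,
                 tolerance = 1e-12)
    expect_equal(voldiff(a, b)$data, a$data - b$data, tolerance = 1e-12)
    expect_equal(volmult(a, b)$data, a$data * b$data, tolerance = 1e-12)
  }
  a <- random_map(c(4, 4, 4))
  expect_equal(volaver(list(a, a))$data, a$data)
  neg <- volume_map(-a$data, a$width, a$origin)
  expect_equal(max(abs(volaver(list(a, neg))$data)), 0)
  expect_equal(voldiff(a, a)$data, array(0, c(4, 4, 4)))
  expect_equal(voldiff(a, neg)$data, -voldiff(neg, a)$data)
})

test_that("lattice mismatches are strict errors", {
  a <- random_map(c(4, 4, 4), width = 1)
  b <- random_map(c(4, 4, 4), width = 2)
  expect_error(voldiff(a, b), "lattice")
  c2 <- random_map(c(4, 4, 4), width = 1, origin = c(1, 0, 0))
  expect_error(volmult(a, c2), "lattice")
  expect_error(volaver(list()), "empty")
})

test_that("binary masking zeroes exactly the mask complement", {
  a <- random_map(c(5, 5, 5), seed = 8)
  mask <- volume_map(array(as.numeric(stats::runif(125) > 0.5), c(5, 5, 5)),
                     a$width, a$origin)
  out <- volmult(a, mask, binary = TRUE)
  expect_equal(out$data[mask$data == 0], rep(0, sum(mask$data == 0)))
  expect_equal(out$data[mask$data == 1], a$data[mask$data == 1])
  ones <- volume_map(array(1, c(5, 5, 5)), a$width, a$origin)
  expect_equal(volmult(a, ones, binary = TRUE)$data, a$data)
  badmask <- volume_map(array(0.5, c(5, 5, 5)), a$width, a$origin)
  expect_error(volmult(a, badmask, binary = TRUE), "binary")
})

test_that("affine density matching recovers exact affine relations", {
  s <- random_map(c(6, 6, 6), seed = 30)
  r <- volume_map(2 * s$data + 3, s$width, s$origin)
  out <- volhist_match(s, r)
  expect_equal(attr(out, "alpha"), 2, tolerance = 1e-12)
  expect_equal(attr(out, "beta"), 3, tolerance = 1e-12)
  expect_equal(out$data, r$data, tolerance = 1e-12)
  self <- volhist_match(s, s)
  expect_equal(attr(self, "alpha"), 1, tolerance = 1e-12)
  expect_equal(attr(self, "beta"), 0, tolerance = 1e-10)
})

test_that("affine matching equals the normal equations and is a minimum", {
  set.seed(31)
  s <- random_map(c(5, 5, 5))
  r <- random_map(c(5, 5, 5))
  out <- volhist_match(s, r)
  sv <- as.vector(s$data); rv <- as.vector(r$data)
  beta_hat <- coef(lm(rv ~ sv))
  expect_equal(attr(out, "alpha"), unname(beta_hat[2]), tolerance = 1e-9)
  expect_equal(attr(out, "beta"), unname(beta_hat[1]), tolerance = 1e-9)
  rss <- function(al, be) sum((al * sv + be - rv)^2)
  r0 <- rss(attr(out, "alpha"), attr(out, "beta"))
  for (da in c(-0.05, 0.05)) for (db in c(-0.05, 0.05))
    expect_gt(rss(attr(out, "alpha") + da, attr(out, "beta") + db), r0)
  flat <- volume_map(array(1, c(5, 5, 5)), s$width, s$origin)
  expect_error(volhist_match(flat, r), "variance")
})

test_that("crop and pad shift the origin consistently and invert", {
  m <- random_map(c(6, 5, 4), width = 2, origin = c(1, 2, 3), seed = 12)
  padded <- crop_pad(m, lo_voxels = -c(2, 1, 0), hi_voxels = -c(1, 2, 3))
  expect_equal(padded$origin, m$origin - 2 * c(2, 1, 0))
  expect_equal(padded$dims, m$dims + c(2, 1, 0) + c(1, 2, 3))
  # content preserved under pure padding
  expect_equal(padded$data[3:8, 2:6, 1:4], m$data)
  back <- crop_pad(padded, lo_voxels = c(2, 1, 0), hi_voxels = c(1, 2, 3))
  expect_equal(back$data, m$data)
  expect_equal(back$origin, m$origin)
  expect_error(crop_pad(m, lo_voxels = c(6, 0, 0)), "crop")
})

test_that("thresholding keeps values at or above the level", {
  m <- random_map(c(5, 5, 5), seed = 14)
  expect_equal(threshold_map(m, min(m$data))$data, m$data)
  expect_equal(max(abs(threshold_map(m, max(m$data) + 1)$data)), 0)
  lvl <- stats::median(m$data)
  out <- threshold_map(m, lvl)
  expect_equal(sum(out$data != 0), sum(sort(as.vector(m$data)) >= lvl))
  expect_true(all(out$data[out$data != 0] >= lvl))
})

test_that("projection integrates mass and commutes with differences", {
  m <- random_map(c(5, 6, 7), width = 1.5, seed = 15)
  p <- project_map(m, "z")
  expect_equal(sum(p$data), sum(m$data) * m$width, tolerance = 1e-12)
  # slice of a constant map is constant
  const <- volume_map(array(4, c(5, 6, 7)), 1.5)
  expect_equal(unique(as.vector(slice_map(const, "y", 3)$data)), 4)
  # projection of a difference equals the difference of projections
  set.seed(16)
  for (axis in c("x", "y", "z")) {
    a <- random_map(c(6, 6, 6), width = 2)
    b <- random_map(c(6, 6, 6), width = 2)
    lhs <- project_map(voldiff(a, b), axis)
    rhs <- voldiff2d(project_map(a, axis), project_map(b, axis))
    expect_lt(max(abs(lhs$data - rhs$data)), 1e-10)
  }
})

test_that("connected-component labels partition the super-threshold set", {
  d <- array(0, c(8, 8, 8))
  d[2:3, 2:3, 2:3] <- 1          # blob A, total 8
  d[6:7, 6:7, 6:7] <- 2          # blob B, total 16 -> label 1
  m <- volume_map(d, 1)
  seg <- segment_connected(m, 0.5)
  expect_equal(seg$n, 2L)
  expect_equal(sort(unique(as.vector(seg$labels))), c(0L, 1L, 2L))
  expect_equal(seg$labels[6, 6, 6], 1L)   # denser blob gets label 1
  expect_equal(seg$labels[2, 2, 2], 2L)
  expect_equal(sum(seg$labels > 0), sum(d >= 0.5))
  # face-diagonal voxels are NOT 6-connected
  d2 <- array(0, c(4, 4, 4)); d2[1, 1, 1] <- 1; d2[2, 2, 1] <- 1
  expect_equal(segment_connected(volume_map(d2, 1), 0.5)$n, 2L)
})

test_that("segmentation agrees with a flood-fill oracle on random maps", {
  set.seed(17)
  flood_oracle <- function(sel) {
    d <- dim(sel); lab <- array(0L, d); n <- 0L
    for (s in which(sel)) {
      if (lab[s]) next
      n <- n + 1L
      stack <- s
      while (length(stack)) {
        cur <- stack[1]; stack <- stack[-1]
        if (lab[cur]) next
        lab[cur] <- n
        ijk <- arrayInd(cur, d)
        for (a in 1:3) for (dd in c(-1, 1)) {
          nb <- ijk; nb[a] <- nb[a] + dd
          if (nb[a] >= 1 && nb[a] <= d[a]) {
            li <- nb[1] + (nb[2] - 1) * d[1] + (nb[3] - 1) * d[1] * d[2]
            if (sel[li] && !lab[li]) stack <- c(stack, li)
          }
        }
      }
    }
    list(lab = lab, n = n)
  }
  for (rep in 1:3) {
    m <- random_map(c(6, 6, 6))
    seg <- segment_connected(m, 0.4)
    ora <- flood_oracle(m$data >= 0.4)
    expect_equal(seg$n, ora$n)
    # same partition up to label permutation
    if (ora$n > 0) {
      pairs <- unique(cbind(as.vector(seg$labels), as.vector(ora$lab)))
      pairs <- pairs[pairs[, 1] > 0, , drop = FALSE]
      expect_equal(nrow(pairs), ora$n)
    }
  }
})

test_that("resampling onto the same lattice is the identity", {
  m <- blob_map(c(8, 8, 8), width = 2)
  r <- resample_to(m, m)
  expect_equal(r$data, m$data, tolerance = 1e-12)
  # resampling a smooth blob at double resolution interpolates its values
  fine <- resample_to(m, list(width = 1, origin = m$origin + 2,
                              dims = c(8, 8, 8)))
  expect_equal(fine$data[1, 1, 1], m$data[2, 2, 2], tolerance = 1e-12)
})
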