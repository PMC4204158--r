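# SDF construction, centroid alignment, shape distance, KDE energy and flow.

test_that("SDF of a disk has the right center value and boundary zero crossing", {
  d <- c(64L, 64L)
  m <- disk_mask(d, 32, 32, 10)
  phi <- sdf_from_mask(m)
  expect_gte(phi[32, 32], 9)
  expect_lte(phi[32, 32], 10.5)
  # every zero crossing lies within one pixel of the mask boundary
  bdry <- m == 1 & (rbind(m[-1, ], m[64, ]) == 0 | rbind(m[1, ], m[-64, ]) == 0 |
                    cbind(m[, -1], m[, 64]) == 0 | cbind(m[, 1], m[, -64]) == 0)
  near <- abs(phi) <= 1
  expect_true(all(abs(phi[bdry]) <= 1))
  expect_true(any(near))
  # complement negates the SDF exactly under this transform pair
  expect_equal(sdf_from_mask(1 - m), -phi)
  expect_error(sdf_from_mask(matrix(1, 8, 8)), "degenerate")
  expect_error(sdf_from_mask(matrix(0, 8, 8)), "degenerate")
})

test_that("centroid is symmetric, equivariant and additive", {
  d <- c(64L, 64L)
  phi <- sdf_from_mask(disk_mask(d, 30, 28, 9))
  expect_equal(centroid(phi), c(30, 28), tolerance = 0.1)
  # translation equivariance
  phi2 <- shift_bilinear(phi, -3, 2)      # object moves by (+3, -2)
  expect_equal(centroid(phi2), c(33, 26), tolerance = 0.05)
  # two equal disks: centroid at the midpoint
  m <- pmax(disk_mask(d, 20, 20, 7), disk_mask(d, 44, 40, 7))
  expect_equal(centroid(sdf_from_mask(m)), c(32, 30), tolerance = 0.1)
})

test_that("shape distance vanishes on identity and ignores translation", {
  d <- c(64L, 64L)
  lib <- build_library(list(disk_mask(d, 32, 32, 12), disk_mask(d, 30, 35, 15)))
  ctr <- c(32.5, 32.5)
  expect_identical(shape_distance2(lib$phi[[1]], lib$phi[[1]], mu = ctr), 0)
  phi <- sdf_from_mask(disk_mask(d, 35, 28, 13))
  d0 <- shape_distance2(phi, lib$phi[[1]])
  for (v in list(c(3, -2), c(-3.5, 2), c(0.5, 0.5))) {
    dv <- shape_distance2(shift_bilinear(phi, v[1], v[2]), lib$phi[[1]])
    expect_lt(abs(dv - d0) / d0, 0.005)
  }
  # pre-aligned arguments: symmetric, nonnegative
  d12 <- shape_distance2(lib$phi[[1]], lib$phi[[2]], mu = ctr)
  d21 <- shape_distance2(lib$phi[[2]], lib$phi[[1]], mu = ctr)
  expect_equal(d12, d21, tolerance = 1e-10)
  expect_gt(d12, 0)
})

test_that("concentric disks give the symmetric-difference area with a sharp kernel", {
  d <- c(64L, 64L)
  m1 <- disk_mask(d, 32.5, 32.5, 10)
  m2 <- disk_mask(d, 32.5, 32.5, 14)
  a1 <- sum(m1); a2 <- sum(m2)
  phi1 <- sdf_from_mask(m1); phi2 <- sdf_from_mask(m2)
  d2 <- shape_distance2(phi1, phi2, eps = 1e-3, mu = c(32.5, 32.5))
  expect_equal(d2, abs(a2 - a1), tolerance = 0.05)
})

test_that("library building aligns shapes and estimates the kernel width", {
  d <- c(64L, 64L)
  masks <- list(disk_mask(d, 28, 30, 10), disk_mask(d, 36, 34, 12),
                disk_mask(d, 32, 32, 14))
  lib <- build_library(masks)
  for (p in lib$phi)
    expect_equal(centroid(p), c(32.5, 32.5), tolerance = 0.1)
  expect_equal(lib$pairwise_d2, t(lib$pairwise_d2))
  expect_equal(diag(lib$pairwise_d2), rep(0, 3))
  nn <- vapply(1:3, function(i) min(lib$pairwise_d2[i, -i]), numeric(1))
  expect_equal(lib$sigma2, mean(nn), tolerance = 1e-12)
  # N = 2: both nearest-neighbor distances equal the single pairwise d2
  lib2 <- build_library(masks[1:2])
  expect_equal(lib2$sigma2, lib2$pairwise_d2[1, 2], tolerance = 1e-12)
  # duplicates make the width estimate zero
  expect_error(build_library(list(masks[[1]], masks[[1]])), "sigma2")
  expect_error(build_library(masks[1]), "sigma2")
  expect_silent(build_library(masks[1], sigma2 = 5))
})

test_that("KDE energy and weights match closed-form arithmetic", {
  d <- c(64L, 64L)
  masks <- list(disk_mask(d, 32, 32, 11), disk_mask(d, 32, 32, 15))
  libd <- build_library(masks)
  D <- libd$pairwise_d2[1, 2]
  # force d2 = (0, 2 sigma2) by choosing sigma2 = D / 2
  lib <- build_library(masks, sigma2 = D / 2)
  ctr <- c(32.5, 32.5)
  E <- shape_energy(lib$phi[[1]], lib, mu = ctr)
  expect_equal(E, -log((1 + exp(-1)) / 2), tolerance = 1e-6)
  al <- shape_weights(lib$phi[[1]], lib, mu = ctr)
  expect_equal(al, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-6)
  # N = 1 at the training shape: energy 0
  lib1 <- build_library(masks[1], sigma2 = 10)
  expect_equal(shape_energy(lib1$phi[[1]], lib1, mu = ctr), 0,
               tolerance = 1e-12)
})

test_that("weights sum to one and concentrate as the kernel sharpens", {
  masks <- small_ring_family(4, seed = 8)
  lib <- build_library(masks)
  set.seed(9)
  phi <- sdf_from_mask(masks[[2]])
  al <- shape_weights(phi, lib)
  expect_equal(sum(al), 1, tolerance = 1e-12)
  expect_true(all(al >= 0 & al <= 1))
  d2 <- gpfseg:::library_d2(phi, lib)$d2
  sharp <- build_library(masks, sigma2 = 1e-3)
  expect_equal(which.max(shape_weights(phi, sharp)), which.min(d2))
})

test_that("shape gradient flow is the frozen-centroid descent direction", {
  d <- c(64L, 64L)
  masks <- small_ring_family(4, seed = 3)
  lib <- build_library(masks)
  phi <- sdf_from_mask(disk_mask(d, 33, 30, 12))
  mu <- centroid(phi)
  sf <- shape_gradient_flow(phi, lib, mu = mu)
  expect_equal(sf$weights, shape_weights(phi, lib, mu = mu), tolerance = 1e-12)
  # directional finite differences against the energy
  for (s in 1:2) {
    psi <- smooth_field(d, seed = 20 + s)
    h <- 1e-4
    fd <- (shape_energy(phi + h * psi, lib, mu = mu) -
           shape_energy(phi - h * psi, lib, mu = mu)) / (2 * h)
    expect_equal(-sum(sf$flow * psi), fd, tolerance = 0.01 * abs(fd))
  }
  # a small explicit step decreases the energy
  t0 <- 0.05 / max(abs(sf$flow))
  expect_lt(shape_energy(phi + t0 * sf$flow, lib, mu = mu), sf$energy)
  # single-shape library at its own shape: zero flow
  lib1 <- build_library(masks[1], sigma2 = 100)
  sf1 <- shape_gradient_flow(lib1$phi[[1]], lib1, mu = c(32.5, 32.5))
  expect_lt(max(abs(sf1$flow)), 1e-10)
})

test_that("shape energy is translation invariant", {
  d <- c(64L, 64L)
  lib <- build_library(small_ring_family(4, seed = 5))
  phi <- sdf_from_mask(disk_mask(d, 32, 30, 11))
  E0 <- shape_energy(phi, lib)
  for (v in list(c(2, 3), c(-1.5, 0.5))) {
    Ev <- shape_energy(shift_bilinear(phi, v[1], v[2]), lib)
    expect_lt(abs(Ev - E0) / abs(E0), 0.005)
  }
})
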