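# Regularized functions, flow assembly, narrow-band evolution, contours.

test_that("regularized Heaviside has the arctan closed form", {
  expect_equal(heaviside_eps(0, 1), 0.5)
  expect_equal(heaviside_eps(1, 1), 0.75)
  z <- seq(-20, 20, by = 0.37)
  expect_equal(heaviside_eps(z, 2) + heaviside_eps(-z, 2), rep(1, length(z)))
  expect_true(all(diff(heaviside_eps(z, 0.5)) > 0))
})

test_that("regularized delta is the derivative of the Heaviside and integrates to 1", {
  expect_equal(dirac_eps(0, 1), 1 / pi)
  expect_equal(dirac_eps(0, 0.25), 1 / (pi * 0.25))
  z <- seq(-10, 10, by = 0.1)
  h <- 1e-5
  fd <- (heaviside_eps(z + h, 1.3) - heaviside_eps(z - h, 1.3)) / (2 * h)
  expect_equal(fd, dirac_eps(z, 1.3), tolerance = 1e-6)
  zz <- seq(-1000, 1000, by = 0.05)
  integ <- sum((dirac_eps(zz[-1], 1) + dirac_eps(zz[-length(zz)], 1)) / 2) * 0.05
  expect_equal(integ, 1, tolerance = 1e-3)
})

test_that("curvature term matches the analytic circle and vanishes on a line", {
  d <- c(64L, 64L)
  g1 <- matrix(1, d[1], d[2])
  expect_equal(curvature_term(phi_init_circle(d, 32, 32, 20), g1, 0),
               matrix(0, 64, 64))
  phi <- phi_init_circle(d, 32.5, 32.5, 20)
  K <- curvature_term(phi, g1, 1)
  ring <- abs(phi) < 0.5
  expect_equal(mean(K[ring]), -1 / 20, tolerance = 0.2 * (1 / 20))
  # straight edge: zero curvature
  half <- matrix(rep(seq_len(64) - 32.5, 64), 64, 64)  # phi = row - 32.5
  Kh <- curvature_term(half, g1, 1)
  expect_lt(max(abs(Kh[abs(half) < 5])), 1e-3)
})

test_that("image flow is Dirac-localized around the interface", {
  d <- c(32L, 32L)
  phi <- phi_init_circle(d, 16, 16, 8)
  z <- matrix(0, 32, 32)
  cfg <- evolution_config(rho = 0)
  expect_equal(image_flow(phi, z, matrix(1, 32, 32), cfg), z)
  G <- matrix(1, 32, 32)
  fl <- image_flow(phi, G, matrix(1, 32, 32), cfg)
  on_if <- max(abs(fl[abs(phi) < 0.5]))
  far <- max(abs(fl[abs(phi) > 10]))
  expect_lt(far, 0.02 * on_if)
})

test_that("auto nu follows the max-ratio heuristic and scales with contrast", {
  d <- c(64L, 64L)
  lib <- build_library(small_ring_family(3, seed = 12))
  phi0 <- sdf_from_mask(disk_mask(d, 30, 34, 12))
  G <- matrix(0, d[1], d[2]); G[10, 10] <- 100
  sf <- shape_gradient_flow(phi0, lib)
  expect_equal(auto_nu(G, phi0, lib, 0.5), 0.5 * 100 / max(abs(sf$flow)))
  expect_equal(auto_nu(2 * G, phi0, lib, 0.5),
               2 * auto_nu(G, phi0, lib, 0.5))
  expect_equal(auto_nu(G, phi0, lib, 0), 0)
  # infinitely wide kernel: no shape force at all, heuristic must refuse
  flat <- build_library(small_ring_family(3, seed = 12), sigma2 = Inf)
  expect_error(auto_nu(G, phi0, flat, 0.5), "manually")
})

test_that("evolution recovers a clean disk from inside, outside and across", {
  di <- disk_image()
  cfg <- evolution_config(max_iters = 500,
                          gpf = gpf_params(presmooth_median = 0))
  for (init in list(c(32, 32, 6), c(32, 14, 8), c(32, 32, 26))) {
    res <- evolve(di$image, phi_init_circle(c(64L, 64L), init[1], init[2], init[3]),
                  NULL, cfg)
    expect_gte(dice(res$mask, di$mask), 0.98)
  }
})

test_that("evolution validates its inputs", {
  di <- disk_image()
  expect_error(evolve(di$image, matrix(1, 64, 64), NULL), "zero crossing")
  expect_error(evolve(di$image, phi_init_circle(c(32L, 32L), 16, 16, 5), NULL),
               "grid")
})

test_that("narrow-band and full-domain evolution agree", {
  di <- disk_image()
  phi0 <- phi_init_circle(c(64L, 64L), 30, 34, 12)
  cfgb <- evolution_config(max_iters = 400, band_halfwidth = 6,
                           gpf = gpf_params(presmooth_median = 0))
  cfgf <- evolution_config(max_iters = 400, band_halfwidth = Inf,
                           gpf = gpf_params(presmooth_median = 0))
  rb <- evolve(di$image, phi0, NULL, cfgb)
  rf <- evolve(di$image, phi0, NULL, cfgf)
  expect_gte(dice(rb$mask, rf$mask), 0.99)
})

test_that("evolution is deterministic", {
  st <- disk_image()
  cfg <- evolution_config(max_iters = 60)
  r1 <- evolve(st$image, phi_init_circle(c(64L, 64L), 32, 32, 10), NULL, cfg)
  r2 <- evolve(st$image, phi_init_circle(c(64L, 64L), 32, 32, 10), NULL, cfg)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$phi, r2$phi)
})

test_that("reinitialization preserves the zero level set to sub-pixel accuracy", {
  phi <- phi_init_circle(c(64L, 64L), 32.3, 31.6, 12.37)
  p2 <- gpfseg:::sdf_reinit(phi)
  near <- abs(phi) < 2
  expect_lt(max(abs(p2[near] - phi[near])), 0.5)
  # |grad phi| ~ 1 on most of the band after reinitialization
  gx <- (p2[, c(2:64, 64)] - p2[, c(1, 1:63)]) / 2
  gy <- (p2[c(2:64, 64), ] - p2[c(1, 1:63), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  band <- abs(p2) > 1 & abs(p2) < 6
  expect_gte(mean(abs(mag[band] - 1) < 0.1), 0.9)
})

test_that("contours are extracted as closed sub-pixel polylines", {
  d <- c(64L, 64L)
  cont <- extract_contour(phi_init_circle(d, 32, 32, 10))
  expect_length(cont, 1L)
  rad <- sqrt((cont[[1]]$y - 32)^2 + (cont[[1]]$x - 32)^2)
  expect_equal(mean(rad), 10, tolerance = 0.02)
  expect_true(all(abs(rad - 10) < 0.2))
  expect_warning(empty <- extract_contour(matrix(1, 8, 8)), "zero crossing")
  expect_length(empty, 0L)
  two <- pmax(phi_init_circle(d, 20, 20, 7), phi_init_circle(d, 44, 44, 7))
  expect_length(extract_contour(two), 2L)
})
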