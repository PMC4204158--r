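# Shared fixture builders; everything is generated in code.

disk_mask <- function(d, cy, cx, r) (phi_init_circle(d, cy, cx, r) >= 0) * 1

random_vf <- function(h, w, seed) {
  set.seed(seed)
  list(vy = matrix(rnorm(h * w), h, w), vx = matrix(rnorm(h * w), h, w))
}

# clean two-level disk image
disk_image <- function(d = c(64L, 64L), cy = 32, cx = 32, r = 18,
                       fg = 0.9, bg = 0.1) {
  m <- disk_mask(d, cy, cx, r)
  list(image = bg + (fg - bg) * m, mask = m)
}

# smooth random field supported away from the grid border
smooth_field <- function(d, seed, margin = 8L, sigma = 3) {
  set.seed(seed)
  psi <- matrix(0, d[1L], d[2L])
  ri <- (margin + 1L):(d[1L] - margin)
  ci <- (margin + 1L):(d[2L] - margin)
  psi[ri, ci] <- rnorm(length(ri) * length(ci))
  EBImage::imageData(EBImage::gblur(psi, sigma = sigma))
}

# small training family of deformed annuli on a 64x64 grid
small_ring_family <- function(n = 5L, seed = 2L) {
  base <- annulus_spec(centers = list(c(32, 32)), outer_radii = 13,
                       inner_radii = 7, noise_fraction = 0)
  make_training_shapes(n, base, deform = list(radial_amp = 0.12,
                                              boundary_smoothness = 3,
                                              jitter = 1.5),
                       shape = c(64L, 64L), seed = seed)
}
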