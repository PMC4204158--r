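#' Gradient-vector-interaction field (geometric potential field)
#'
#' The image feature driving the contour is a scalar field built from the
#' long-range interaction of all image gradient vectors: every pixel x
#' receives, from every other pixel x', the projection of the gradient
#' vector at x' onto the unit vector pointing from x to x', attenuated by an
#' inverse power of the pixel distance,
#' \deqn{G(x) = \sum_{x' \ne x} \frac{\hat r_{xx'}}{r_{xx'}^{\lambda}}
#'       \cdot \nabla I(x'),}
#' with \eqn{\lambda} equal to the image dimension (2 here).  Unlike the
#' local gradient magnitude, G encodes a coherent global picture of the
#' edge configuration: it changes sign across boundaries (bidirectionality)
#' and is robust to uncorrelated noise, whose randomly oriented gradient
#' vectors cancel in the sum.
#'
#' `gpf_bruteforce()` evaluates the pairwise sum directly (O(n^2), the
#' reference oracle); `gpf_fft()` evaluates the same sum as a zero-padded
#' linear convolution in O(n log n) and is the production path.
#'
#' @name gpf
NULL

pad_replicate1 <- function(m) {
  m2 <- m[c(1L, seq_len(nrow(m)), nrow(m)), , drop = FALSE]
  m2[, c(1L, seq_len(ncol(m)), ncol(m)), drop = FALSE]
}

#' Parameters of the interaction field
#'
#' @param lam Interaction falloff exponent \eqn{\lambda > 0}; defaults to 2,
#'   the image dimensionality.
#' @param edge_threshold_fraction Gradient vectors with magnitude below this
#'   fraction of the maximum magnitude are zeroed before the interaction sum
#'   (suppresses spurious weak edges); in `[0, 1)`, default 0.05.
#' @param derivative_scheme `"central"` (central differences, one-sided at
#'   borders) or `"sobel"` (3x3 Sobel with replicate padding).
#' @param presmooth_median Radius of a median prefilter applied to the
#'   image before differentiation; 0 disables.  The median is the standard
#'   remover of replacement (impulse) noise: it restores corrupted pixels
#'   from their neighborhood majority without displacing edges.  Default 2
#'   (a 5x5 window).
#' @param presmooth_sigma Standard deviation (pixels) of a Gaussian blur
#'   applied after the median, as in Gaussian-derivative edge detection;
#'   0 disables.  Presmoothing is what makes the magnitude threshold
#'   meaningful under heavy noise: it pushes the gradients of corrupted
#'   pixels below the threshold while coherent object edges survive.
#'
#'   Both presmoothing arguments accept equal-length vectors, in which case
#'   the restored image is the average over the `(median, sigma)` scale
#'   pairs.  This scale-space average trades a little edge sharpness for a
#'   much smoother interaction field under very heavy noise, where any
#'   single filtering scale leaves enough residual clutter to pin the
#'   front.
#' @param unit_vectors If `TRUE`, supra-threshold gradient vectors are
#'   normalized to unit length before summation; default `FALSE`
#'   (magnitude-weighted).
#' @return A list of class `"gpf_params"`.
#' @export
gpf_params <- function(lam = 2, edge_threshold_fraction = 0.05,
                       derivative_scheme = c("central", "sobel"),
                       presmooth_median = 2L, presmooth_sigma = 1,
                       unit_vectors = FALSE) {
  derivative_scheme <- match.arg(derivative_scheme)
  stopifnot(is.numeric(lam), length(lam) == 1L, lam > 0,
            is.numeric(edge_threshold_fraction),
            edge_threshold_fraction >= 0, edge_threshold_fraction < 1,
            is.numeric(presmooth_median), all(presmooth_median >= 0),
            is.numeric(presmooth_sigma), all(presmooth_sigma >= 0),
            length(presmooth_median) == length(presmooth_sigma),
            length(presmooth_median) >= 1L,
            is.logical(unit_vectors), length(unit_vectors) == 1L)
  structure(list(lam = lam,
                 edge_threshold_fraction = edge_threshold_fraction,
                 derivative_scheme = derivative_scheme,
                 presmooth_median = as.integer(presmooth_median),
                 presmooth_sigma = presmooth_sigma,
                 unit_vectors = unit_vectors),
            class = "gpf_params")
}

presmooth_one <- function(img, med_r, sigma) {
  if (med_r > 0) {
    rng <- range(img)
    if (rng[1L] < 0 || rng[2L] > 1) {        # medianFilter needs [0, 1]
      sc <- max(rng[2L] - rng[1L], 1e-12)
      img <- EBImage::imageData(EBImage::medianFilter(
        (img - rng[1L]) / sc, med_r)) * sc + rng[1L]
    } else {
      img <- EBImage::imageData(EBImage::medianFilter(img, med_r))
    }
  }
  if (sigma > 0)
    img <- EBImage::imageData(EBImage::gblur(img, sigma = sigma))
  img
}

presmooth <- function(img, params) {
  n <- length(params$presmooth_median)
  if (n == 1L)
    return(presmooth_one(img, params$presmooth_median, params$presmooth_sigma))
  acc <- 0
  for (i in seq_len(n))
    acc <- acc + presmooth_one(img, params$presmooth_median[i],
                               params$presmooth_sigma[i])
  acc / n
}

#' Image gradient estimate
#'
#' @param img Numeric matrix, at least 3x3.
#' @param scheme `"central"` (exact on linear ramps; one-sided differences at
#'   the borders) or `"sobel"` (3x3 Sobel correlation, replicate padding,
#'   normalized so a unit ramp gives gradient 1).
#' @return List with components `vy`, `vx` (same shape as `img`).
#' @export
image_gradient <- function(img, scheme = c("central", "sobel")) {
  scheme <- match.arg(scheme)
  assert_raster(img)
  h <- nrow(img); w <- ncol(img)
  if (scheme == "central") {
    vy <- (img[c(2:h, h), ] - img[c(1L, 1:(h - 1L)), ]) /
      rep(c(1, rep(2, h - 2L), 1), w)
    vx <- (img[, c(2:w, w)] - img[, c(1L, 1:(w - 1L))]) /
      rep(c(1, rep(2, w - 2L), 1), each = h)
  } else {
    p <- pad_replicate1(img)
    sub <- function(dr, dc) p[(2L + dr):(h + 1L + dr), (2L + dc):(w + 1L + dc)]
    # Sobel correlation kernels, /8 so a unit-slope ramp yields 1
    vx <- (-sub(-1L, -1L) + sub(-1L, 1L)
           - 2 * sub(0L, -1L) + 2 * sub(0L, 1L)
           - sub(1L, -1L) + sub(1L, 1L)) / 8
    vy <- (-sub(-1L, -1L) - 2 * sub(-1L, 0L) - sub(-1L, 1L)
           + sub(1L, -1L) + 2 * sub(1L, 0L) + sub(1L, 1L)) / 8
  }
  list(vy = vy, vx = vx)
}

#' Zero out weak gradient vectors
#'
#' Vectors whose magnitude falls below `fraction` of the maximum magnitude
#' are set to zero; the rest are unchanged.
#'
#' @param vf Vector field (list with `vy`, `vx`).
#' @param fraction Threshold fraction in `[0, 1)`.
#' @return Thresholded vector field.
#' @export
threshold_gradients <- function(vf, fraction) {
  stopifnot(fraction >= 0, fraction < 1)
  mag <- sqrt(vf$vy^2 + vf$vx^2)
  mx <- max(mag)
  if (mx == 0 || fraction == 0) return(vf)
  keep <- mag >= fraction * mx
  list(vy = vf$vy * keep, vx = vf$vx * keep)
}

#' Edge-stopping function g = 1 / (1 + |grad I|)
#'
#' Monotone decreasing in the gradient magnitude, in (0, 1]; equals 1 where
#' the image is locally flat.  Weights the curvature (length) term so the
#' contour can settle on strong edges.
#'
#' @inheritParams image_gradient
#' @return Numeric matrix in (0, 1].
#' @export
edge_stopping <- function(img, scheme = c("central", "sobel")) {
  vf <- image_gradient(img, scheme)
  1 / (1 + sqrt(vf$vy^2 + vf$vx^2))
}

unit_normalize <- function(vf) {
  mag <- sqrt(vf$vy^2 + vf$vx^2)
  mag[mag == 0] <- 1
  list(vy = vf$vy / mag, vx = vf$vx / mag)
}

#' Interaction field by direct pairwise summation (reference oracle)
#'
#' O(n^2) in the pixel count; intended for testing the FFT path on small
#' grids, not for production use.
#'
#' @param vf Vector field (list with `vy`, `vx`), typically thresholded.
#' @param params A [gpf_params()] object.
#' @return Numeric matrix G, same shape as the field.
#' @export
gpf_bruteforce <- function(vf, params = gpf_params()) {
  stopifnot(inherits(params, "gpf_params"))
  if (params$unit_vectors) vf <- unit_normalize(vf)
  vy <- vf$vy; vx <- vf$vx
  h <- nrow(vy); w <- ncol(vy)
  R <- matrix(seq_len(h), h, w)
  C <- matrix(seq_len(w), h, w, byrow = TRUE)
  G <- matrix(0, h, w)
  src <- which(vy != 0 | vx != 0)
  ex <- params$lam + 1
  for (s in src) {
    r0 <- R[s]; c0 <- C[s]
    dy <- r0 - R; dx <- c0 - C          # offset from target x to source x'
    d2 <- dy * dy + dx * dx
    d2[s] <- Inf                        # self-interaction excluded
    G <- G + (dy * vy[s] + dx * vx[s]) / d2^(ex / 2)
  }
  G
}

#' Interaction kernel components on a centered offset grid
#'
#' Samples the vector kernel \eqn{k(r) = r / |r|^{\lambda+1}} (with
#' \eqn{k(0) = 0}, excluding self-interaction) on the integer offset grid
#' needed to reproduce the pairwise sum as a linear convolution over a
#' `height` x `width` image.
#'
#' @param height,width Kernel grid size; the grid spans offsets
#'   `-(height-1)/2 .. (height-1)/2` per axis when odd, so a full linear
#'   convolution over an H x W image needs `2H - 1` x `2W - 1`.
#' @param lam Falloff exponent.
#' @return List with matrices `ky`, `kx` and integer vectors `dy`, `dx` of
#'   the offsets along each axis.
#' @export
gpf_kernels <- function(height, width, lam = 2) {
  stopifnot(height >= 1, width >= 1, lam > 0)
  dy <- seq_len(height) - ((height + 1L) %/% 2L)
  dx <- seq_len(width) - ((width + 1L) %/% 2L)
  DY <- matrix(dy, height, width)
  DX <- matrix(dx, height, width, byrow = TRUE)
  d <- sqrt(DY^2 + DX^2)
  d[d == 0] <- Inf
  list(ky = DY / d^(lam + 1), kx = DX / d^(lam + 1), dy = dy, dx = dx)
}

# Kernel sampled with offsets wrapped for a P1 x P2 circular convolution.
kernel_wrapped <- function(p1, p2, lam) {
  dy <- c(0:(p1 %/% 2), -((p1 - p1 %/% 2 - 1L):1L))
  dx <- c(0:(p2 %/% 2), -((p2 - p2 %/% 2 - 1L):1L))
  DY <- matrix(dy, p1, p2)
  DX <- matrix(dx, p1, p2, byrow = TRUE)
  d <- sqrt(DY^2 + DX^2)
  d[1L, 1L] <- Inf
  list(ky = DY / d^(lam + 1), kx = DX / d^(lam + 1))
}

#' Interaction field via zero-padded FFT convolution (production path)
#'
#' Numerically identical to [gpf_bruteforce()] up to floating-point
#' round-off.  The pairwise sum over the finite image domain is a linear,
#' not circular, convolution, so each gradient component is zero-padded to
#' at least `(2H - 1, 2W - 1)` before the FFT and the result is cropped
#' back to the image extent (no wrap-around leakage).
#'
#' @inheritParams gpf_bruteforce
#' @return Numeric matrix G, same shape as the field.
#' @export
gpf_fft <- function(vf, params = gpf_params()) {
  stopifnot(inherits(params, "gpf_params"))
  if (params$unit_vectors) vf <- unit_normalize(vf)
  h <- nrow(vf$vy); w <- ncol(vf$vy)
  p1 <- 2L * h; p2 <- 2L * w
  k <- kernel_wrapped(p1, p2, params$lam)
  pad <- function(m) { z <- matrix(0, p1, p2); z[1:h, 1:w] <- m; z }
  # G(x) = sum_x' k(x' - x) . v(x')  =  conv(v, k~) with k~(u) = k(-u) = -k(u)
  acc <- stats::fft(pad(vf$vy)) * stats::fft(-k$ky) +
         stats::fft(pad(vf$vx)) * stats::fft(-k$kx)
  G <- Re(stats::fft(acc, inverse = TRUE)) / (p1 * p2)
  G[1:h, 1:w]
}

#' Full image-to-feature pipeline
#'
#' Gradient estimation, weak-edge thresholding, edge-stopping function and
#' the FFT interaction field in one call.
#'
#' @param img Numeric matrix (intensities).
#' @param params A [gpf_params()] object.
#' @return List with `G` (interaction field), `g` (edge-stopping function)
#'   and `vf` (the thresholded vector field).
#' @export
gpf_field <- function(img, params = gpf_params()) {
  img <- presmooth(img, params)
  vf <- image_gradient(img, params$derivative_scheme)
  g <- 1 / (1 + sqrt(vf$vy^2 + vf$vx^2))
  vf <- threshold_gradients(vf, params$edge_threshold_fraction)
  list(G = gpf_fft(vf, params), g = g, vf = vf)
}
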