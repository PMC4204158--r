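#' Kernel-density shape prior over signed distance functions
#'
#' Training shapes are represented as signed distance functions (SDFs,
#' positive inside the object) on a common grid, aligned so that their
#' centers of gravity sit at the grid center.  The dissimilarity between an
#' evolving shape phi and a training shape phi_i is the integrated squared
#' difference of their regularized indicator functions after translating
#' phi so its centroid matches the training alignment:
#' \deqn{d^2(\phi, \phi_i) = \int \big(H_\epsilon(\phi(x + \mu_\phi - c)) -
#'       H_\epsilon(\phi_i(x))\big)^2 \, dx,}
#' which is invariant to the location of phi.  A kernel density estimate on
#' this distance gives the shape energy
#' \deqn{E_{shape}(\phi) = -\log \frac1N \sum_i
#'       \exp\!\big(-d^2(\phi,\phi_i) / 2\sigma^2\big),}
#' whose gradient descent pulls phi toward each training shape with weight
#' \eqn{\alpha_i \propto \exp(-d^2_i / 2\sigma^2)}.  Being nonparametric,
#' the prior places no Gaussian assumption on the shape distribution and
#' can represent multimodal families of shapes.
#'
#' @name shape_prior
NULL

grid_center <- function(d) c((d[1L] + 1) / 2, (d[2L] + 1) / 2)

#' Translate a field by a constant (possibly fractional) offset
#'
#' Returns `out[r, c] = m[r + sy, c + sx]` with bilinear interpolation for
#' fractional offsets and replicate (clamped) extension at the borders.
#'
#' @param m Numeric matrix.
#' @param sy,sx Offset in rows / columns (pixels).
#' @return Shifted matrix, same shape.
#' @export
shift_bilinear <- function(m, sy, sx) {
  h <- nrow(m); w <- ncol(m)
  r0 <- floor(sy); ty <- sy - r0
  i0 <- pmin(pmax(seq_len(h) + r0, 1L), h)
  i1 <- pmin(pmax(seq_len(h) + r0 + 1L, 1L), h)
  m <- if (ty == 0) m[i0, , drop = FALSE]
       else (1 - ty) * m[i0, , drop = FALSE] + ty * m[i1, , drop = FALSE]
  c0 <- floor(sx); tx <- sx - c0
  j0 <- pmin(pmax(seq_len(w) + c0, 1L), w)
  j1 <- pmin(pmax(seq_len(w) + c0 + 1L, 1L), w)
  if (tx == 0) m[, j0, drop = FALSE]
  else (1 - tx) * m[, j0, drop = FALSE] + tx * m[, j1, drop = FALSE]
}

#' Signed distance function of a binary mask
#'
#' Exact Euclidean distance transform of the mask and of its complement,
#' combined with the package-wide positive-inside convention:
#' `phi > 0` inside the object, `phi < 0` outside.
#'
#' @param mask Numeric or logical matrix; nonzero marks foreground.  Must
#'   contain at least one foreground and one background pixel.
#' @return Numeric matrix phi.
#' @export
sdf_from_mask <- function(mask) {
  fg <- (mask != 0) * 1
  nfg <- sum(fg)
  if (nfg == 0 || nfg == length(fg))
    stop("degenerate mask: needs at least one foreground and one background pixel",
         call. = FALSE)
  din <- EBImage::imageData(EBImage::distmap(fg))
  dout <- EBImage::imageData(EBImage::distmap(1 - fg))
  matrix(din - dout, nrow(mask), ncol(mask))
}

# Indicator width used for centroid/alignment computations.  The arctan
# Heaviside at eps = 1 has 1/z tails that put nonnegligible mass on the
# whole background of a finite grid and bias the center of gravity; a
# sharp indicator keeps the centroid translation-equivariant to ~0.02 px.
ALIGN_EPS <- 0.05

#' Center of gravity of a shape
#'
#' Mass-weighted mean position under the regularized indicator
#' \eqn{H_\epsilon(\phi)}.  The default width is much sharper than the
#' energy regularization: with a wide Heaviside the slowly decaying tails
#' assign mass to the entire background, which biases the centroid on a
#' finite grid and breaks the translation equivariance the intrinsic
#' alignment relies on.
#'
#' @param phi Level set function (matrix, positive inside).
#' @param eps Heaviside width for the mass weighting.
#' @return Numeric `(row, col)` in pixel coordinates.
#' @export
centroid <- function(phi, eps = ALIGN_EPS) {
  H <- heaviside_eps(phi, eps)
  mass <- sum(H)
  if (mass <= 0) stop("degenerate shape: zero mass", call. = FALSE)
  c(sum(.row_mat(dim(phi)) * H), sum(.col_mat(dim(phi)) * H)) / mass
}

.row_mat <- function(d) matrix(seq_len(d[1L]), d[1L], d[2L])
.col_mat <- function(d) matrix(seq_len(d[2L]), d[1L], d[2L], byrow = TRUE)

# Align phi to the grid center and measure squared indicator distances to a
# list of precomputed training indicators.  mu overrides the centroid
# (frozen-centroid evaluation used by the gradient checks).
aligned_indicator <- function(phi, eps, mu = NULL) {
  ctr <- grid_center(dim(phi))
  if (is.null(mu)) mu <- centroid(phi)
  s <- mu - ctr
  phit <- shift_bilinear(phi, s[1L], s[2L])
  list(phit = phit, Ht = heaviside_eps(phit, eps), s = s)
}

#' Centroid-aligned squared shape distance
#'
#' @param phi Evolving level set (any location on the grid).
#' @param phi_i Training level set, already centroid-aligned at the grid
#'   center.
#' @param eps Heaviside regularization width.
#' @param mu Optional frozen centroid of `phi` (row, col); when `NULL` the
#'   centroid is computed from `phi`.
#' @return Scalar squared distance (pixel area units).
#' @export
shape_distance2 <- function(phi, phi_i, eps = 1, mu = NULL) {
  assert_same_dim(phi, phi_i, "shapes")
  a <- aligned_indicator(phi, eps, mu)
  sum((a$Ht - heaviside_eps(phi_i, eps))^2)
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Build a shape library from binary training masks
#'
#' Each mask is converted to an SDF, translated so its center of gravity
#' sits at the grid center, and stored with its regularized indicator.  The
#' squared kernel width defaults to the mean nearest-neighbor squared
#' distance among the training shapes (the quantity that appears in the
#' KDE exponent).
#'
#' @param masks List of binary matrices on a common grid.
#' @param eps Heaviside regularization width.
#' @param sigma2 Optional kernel width override (squared-distance units);
#'   required when `length(masks) == 1` or when duplicate shapes make the
#'   nearest-neighbor estimate zero.
#' @return An object of class `"shape_library"` with elements `phi`
#'   (aligned SDFs), `H` (their indicators), `sigma2`, `pairwise_d2`,
#'   `eps`, `dim`.
#' @export
build_library <- function(masks, eps = 1, sigma2 = NULL) {
  stopifnot(is.list(masks), length(masks) >= 1L)
  n <- length(masks)
  if (n == 1L && is.null(sigma2))
    stop("a single-shape library requires an explicit 'sigma2'", call. = FALSE)
  d <- dim(masks[[1L]])
  ctr <- grid_center(d)
  phis <- vector("list", n)
  for (i in seq_len(n)) {
    assert_same_dim(masks[[i]], masks[[1L]], "training masks")
    phi <- sdf_from_mask(masks[[i]])
    s <- centroid(phi) - ctr
    phis[[i]] <- shift_bilinear(phi, s[1L], s[2L])
  }
  Hs <- lapply(phis, heaviside_eps, eps = eps)
  d2 <- matrix(0, n, n)
  if (n > 1L) {
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      d2[i, j] <- d2[j, i] <- sum((Hs[[i]] - Hs[[j]])^2)
    }
  }
  if (is.null(sigma2)) {
    nn <- vapply(seq_len(n), function(i) min(d2[i, -i]), numeric(1))
    sigma2 <- mean(nn)
    if (sigma2 <= 0)
      stop("duplicate training shapes give kernel width 0; supply 'sigma2' ",
           "or deduplicate the masks", call. = FALSE)
  }
  stopifnot(sigma2 > 0)
  structure(list(phi = phis, H = Hs, sigma2 = sigma2, pairwise_d2 = d2,
                 eps = eps, dim = d),
            class = "shape_library")
}

#' @export
print.shape_library <- function(x, ...) {
  cat(sprintf("Shape library: %d shapes on a %dx%d grid\n",
              length(x$phi), x$dim[1L], x$dim[2L]))
  cat(sprintf("  kernel width sigma^2 = %.4g, eps = %g\n", x$sigma2, x$eps))
  invisible(x)
}

library_d2 <- function(phi, lib, mu = NULL) {
  a <- aligned_indicator(phi, lib$eps, mu)
  a$d2 <- vapply(lib$H, function(Hi) sum((a$Ht - Hi)^2), numeric(1))
  a
}

#' KDE shape energy
#'
#' \eqn{E_{shape} = -\log\frac1N\sum_i \exp(-d^2_i/2\sigma^2)}, computed
#' with a log-sum-exp shift so it stays finite for any finite distances.
#'
#' @param phi Evolving level set.
#' @param lib A [build_library()] object.
#' @param mu Optional frozen centroid of `phi`.
#' @return Scalar energy (0 when phi coincides with a training shape and
#'   the library has one shape; at most log N in the tight-kernel limit).
#' @export
shape_energy <- function(phi, lib, mu = NULL) {
  d2 <- library_d2(phi, lib, mu)$d2
  -(logsumexp(-d2 / (2 * lib$sigma2)) - log(length(d2)))
}

#' Per-shape KDE weights
#'
#' \eqn{\alpha_i = \exp(-d^2_i/2\sigma^2) / \sum_j \exp(-d^2_j/2\sigma^2)};
#' nonnegative, summing to one, concentrating on the nearest training shape
#' as sigma shrinks.
#'
#' @inheritParams shape_energy
#' @return Numeric vector of length N.
#' @export
shape_weights <- function(phi, lib, mu = NULL) {
  d2 <- library_d2(phi, lib, mu)$d2
  z <- -d2 / (2 * lib$sigma2)
  w <- exp(z - max(z))
  w / sum(w)
}

#' Shape gradient flow
#'
#' Descent direction on the KDE shape energy with respect to phi, holding
#' the alignment offset (the centroid of phi) fixed within the step:
#' \deqn{\partial_t\phi(x) = -\frac{\delta_\epsilon(\phi)}{\sigma^2}
#'       \sum_i \alpha_i\big(H_\epsilon(\phi) -
#'       H_\epsilon(\phi_i(\cdot - \mu_\phi + c))\big),}
#' i.e. a force toward each training shape (mapped back into the image
#' frame) weighted by alpha_i.  The centroid is recomputed every
#' iteration but not differentiated through; the correction term is second
#' order for small steps.
#'
#' @inheritParams shape_energy
#' @return A list of class `"shape_flow"` with `flow` (matrix, descent
#'   direction: adding `t * flow` decreases the energy for small t > 0),
#'   `weights` (alpha), `energy` and `d2`.
#' @export
shape_gradient_flow <- function(phi, lib, mu = NULL) {
  a <- library_d2(phi, lib, mu)
  z <- -a$d2 / (2 * lib$sigma2)
  m <- max(z)
  w <- exp(z - m)
  alpha <- w / sum(w)
  energy <- -(m + log(sum(w)) - log(length(w)))
  resid <- matrix(0, lib$dim[1L], lib$dim[2L])
  for (i in seq_along(alpha)) {
    if (alpha[i] > 1e-300) resid <- resid + alpha[i] * (a$Ht - lib$H[[i]])
  }
  # adjoint of the alignment shift: translate back by -s (aligned -> image)
  fl <- -shift_bilinear(dirac_eps(a$phit, lib$eps) * resid,
                        -a$s[1L], -a$s[2L]) / lib$sigma2
  structure(list(flow = fl, weights = alpha, energy = energy, d2 = a$d2),
            class = "shape_flow")
}
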