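#' Regularized Heaviside and Dirac functions
#'
#' Smooth approximations of the indicator-of-interior and the contour
#' localization terms, in the arctangent form common to region-based level
#' set models:
#' \deqn{H_\epsilon(z) = \tfrac12\left(1 + \tfrac{2}{\pi}\arctan(z/\epsilon)\right),
#'       \qquad \delta_\epsilon(z) = \frac{1}{\pi}\,
#'       \frac{\epsilon}{\epsilon^2 + z^2}.}
#' \eqn{\delta_\epsilon} is the exact derivative of \eqn{H_\epsilon} and
#' integrates to 1 over the real line.  The default width
#' \eqn{\epsilon = 1} (one pixel) gives every grid point a nonzero, rapidly
#' decaying weight, which lets the contour react to features a few pixels
#' away.
#'
#' @param z Numeric vector, matrix or array (level set values).
#' @param eps Positive regularization width, in pixels.
#' @return Object shaped like `z`.
#' @examples
#' heaviside_eps(0, 1)   # 0.5
#' heaviside_eps(1, 1)   # 0.75
#' dirac_eps(0, 1)       # 1/pi
#' @export
heaviside_eps <- function(z, eps = 1) {
  stopifnot(eps > 0)
  0.5 * (1 + (2 / pi) * atan(z / eps))
}

#' @rdname heaviside_eps
#' @export
dirac_eps <- function(z, eps = 1) {
  stopifnot(eps > 0)
  (eps / pi) / (eps^2 + z^2)
}
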