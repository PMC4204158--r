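#' Synthetic annulus phantoms
#'
#' Generators for the study conditions the package is exercised on: images
#' containing several annulus-like (ring) objects on a darker background,
#' degraded by a linear intensity ramp (emulating bias-field-like
#' inhomogeneity), impulse "replacement" noise (a stated fraction of all
#' pixels replaced by random draws), and optional occlusions; plus families
#' of smoothly deformed training rings for the shape prior.  Every
#' generator is a pure function of its spec and seed.
#'
#' @name fixtures
NULL

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Annulus image specification
#'
#' @param centers List of `(row, col)` annulus centers.
#' @param outer_radii,inner_radii Radii per annulus (pixels),
#'   `inner < outer`.
#' @param fg_level,bg_level Ring and background intensities in `[0, 1]`.
#' @param intensity_gradient `(gy, gx)` slope of the additive linear ramp
#'   (intensity per pixel).
#' @param noise_fraction Fraction of all pixels replaced by noise draws, in
#'   `[0, 1]`.
#' @param noise_kind `"replace_gaussian"` (draws from N(0.5, 0.5) clipped to
#'   `[0, 1]`) or `"replace_uniform"` (uniform on `[0, 1]`).
#' @param occlusion Optional occlusion forced to `bg_level` in the image
#'   only: `list(type = "disk", center = c(y, x), radius = r)` or
#'   `list(type = "sector", center = c(y, x), radius = r, theta = c(a, b))`
#'   (angles in radians, measured from the +x axis).
#' @param seed Integer seed; the generator is deterministic given the spec.
#' @return A list of class `"annulus_spec"`.
#' @export
annulus_spec <- function(centers = list(c(40, 44), c(88, 82)),
                         outer_radii = c(20, 22), inner_radii = c(11, 12),
                         fg_level = 0.7, bg_level = 0.1,
                         intensity_gradient = c(0.001, 0.001),
                         noise_fraction = 0.4,
                         noise_kind = c("replace_gaussian", "replace_uniform"),
                         occlusion = NULL, seed = 1L) {
  noise_kind <- match.arg(noise_kind)
  stopifnot(is.list(centers), length(centers) >= 1L,
            length(outer_radii) == length(centers),
            length(inner_radii) == length(centers),
            all(inner_radii < outer_radii), all(inner_radii > 0),
            noise_fraction >= 0, noise_fraction <= 1,
            fg_level >= 0, fg_level <= 1, bg_level >= 0, bg_level <= 1,
            length(intensity_gradient) == 2L)
  structure(list(centers = centers, outer_radii = outer_radii,
                 inner_radii = inner_radii, fg_level = fg_level,
                 bg_level = bg_level,
                 intensity_gradient = intensity_gradient,
                 noise_fraction = noise_fraction, noise_kind = noise_kind,
                 occlusion = occlusion, seed = as.integer(seed)),
            class = "annulus_spec")
}

annulus_mask <- function(spec, d, centers = spec$centers,
                         outer = spec$outer_radii, inner = spec$inner_radii,
                         pert_out = NULL, pert_in = NULL) {
  R <- .row_mat(d); C <- .col_mat(d)
  m <- matrix(FALSE, d[1L], d[2L])
  for (j in seq_along(centers)) {
    dy <- R - centers[[j]][1L]; dx <- C - centers[[j]][2L]
    r <- sqrt(dy^2 + dx^2)
    ro <- outer[j]; ri <- inner[j]
    if (!is.null(pert_out)) {
      th <- atan2(dy, dx)
      ro <- ro * (1 + pert_out[[j]](th))
      ri <- ri * (1 + pert_in[[j]](th))
    }
    m <- m | (r >= ri & r <= ro)
  }
  m
}

check_fit <- function(centers, outer, d) {
  for (j in seq_along(centers)) {
    cy <- centers[[j]][1L]; cx <- centers[[j]][2L]; ro <- outer[j]
    if (cy - ro < 2 || cx - ro < 2 || cy + ro > d[1L] - 1 || cx + ro > d[2L] - 1)
      stop("annulus ", j, " overlaps the image border", call. = FALSE)
  }
}

#' Generate an annulus phantom image and its ground-truth mask
#'
#' The clean two-level image is built first, the linear intensity ramp is
#' added, the occlusion (if any) is forced to the background level, and
#' finally exactly `round(noise_fraction * H * W)` pixels, chosen without
#' replacement by the seeded generator, are replaced by noise draws.  The
#' ground-truth mask is the full (unoccluded, noise-free) union of the
#' rings, so recovery of occluded parts can be scored against the complete
#' object.
#'
#' @param spec An [annulus_spec()].
#' @param shape Grid size `c(rows, cols)`.
#' @return List with `image` and `mask` matrices.
#' @export
make_annulus_image <- function(spec, shape = c(128L, 128L)) {
  stopifnot(inherits(spec, "annulus_spec"))
  d <- as.integer(shape)
  check_fit(spec$centers, spec$outer_radii, d)
  mask <- annulus_mask(spec, d)
  img <- spec$bg_level + (spec$fg_level - spec$bg_level) * mask
  img <- img + spec$intensity_gradient[1L] * (.row_mat(d) - 1) +
    spec$intensity_gradient[2L] * (.col_mat(d) - 1)
  if (!is.null(spec$occlusion)) {
    occ <- spec$occlusion
    dy <- .row_mat(d) - occ$center[1L]; dx <- .col_mat(d) - occ$center[2L]
    r <- sqrt(dy^2 + dx^2)
    inside <- r <= occ$radius
    if (identical(occ$type, "sector")) {
      th <- atan2(dy, dx)
      a <- occ$theta[1L]; b <- occ$theta[2L]
      inside <- inside & if (a <= b) th >= a & th <= b else th >= a | th <= b
    }
    img[inside] <- spec$bg_level
  }
  n_noise <- round(spec$noise_fraction * prod(d))
  if (n_noise > 0) {
    with_seed(spec$seed, {
      idx <- sample.int(prod(d), n_noise)
      draws <- if (spec$noise_kind == "replace_gaussian")
        pmin(pmax(stats::rnorm(n_noise, 0.5, 0.5), 0), 1)
      else stats::runif(n_noise)
      img[idx] <- draws
    })
  }
  list(image = img, mask = mask * 1L)
}

smooth_pert <- function(amp, k_max) {
  if (amp == 0) return(function(th) 0 * th)
  ks <- seq_len(k_max)
  a <- stats::rnorm(k_max); b <- stats::rnorm(k_max)
  scale <- amp * stats::runif(1, 0.6, 1) / sqrt(sum(a^2 + b^2) / 2)
  function(th) {
    out <- 0
    for (k in ks) out <- out + a[k] * cos(k * th) + b[k] * sin(k * th)
    scale * out
  }
}

#' Generate a family of deformed training rings
#'
#' Each training mask perturbs every annulus of the base spec by smooth
#' band-limited radial functions (harmonics up to `boundary_smoothness`)
#' applied to the inner and outer radii, and jitters the centers.  Shapes
#' whose rings would self-intersect (inner meeting outer) or break into
#' extra connected components are regenerated, up to a retry cap.
#'
#' @param n Number of training shapes (>= 2).
#' @param base An [annulus_spec()] giving the nominal geometry.
#' @param deform List with `radial_amp` (relative radial amplitude),
#'   `boundary_smoothness` (highest harmonic), `jitter` (max center shift,
#'   pixels).
#' @param shape Grid size `c(rows, cols)`.
#' @param seed Integer seed.
#' @return List of `n` binary (0/1) matrices.
#' @export
make_training_shapes <- function(n, base,
                                 deform = list(radial_amp = 0.12,
                                               boundary_smoothness = 4,
                                               jitter = 2),
                                 shape = c(128L, 128L), seed = 1L) {
  stopifnot(n >= 2, inherits(base, "annulus_spec"))
  d <- as.integer(shape)
  amp <- deform$radial_amp %||% 0.12
  kmax <- deform$boundary_smoothness %||% 4
  jit <- deform$jitter %||% 2
  n_ann <- length(base$centers)
  n_comp_base <- max(EBImage::bwlabel(annulus_mask(base, d)))
  with_seed(seed, {
    out <- vector("list", n)
    th_grid <- seq(0, 2 * pi, length.out = 512L)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in 1:50) {
        centers <- lapply(base$centers, function(cc)
          cc + stats::runif(2, -jit, jit))
        po <- replicate(n_ann, smooth_pert(amp, kmax), simplify = FALSE)
        pi_ <- replicate(n_ann, smooth_pert(amp / 2, kmax), simplify = FALSE)
        # reject rings that pinch shut or leave the grid
        good <- TRUE
        for (j in seq_len(n_ann)) {
          ro <- base$outer_radii[j] * (1 + po[[j]](th_grid))
          ri <- base$inner_radii[j] * (1 + pi_[[j]](th_grid))
          if (min(ro - ri) < 2 || min(ri) < 1 ||
              centers[[j]][1L] - max(ro) < 2 ||
              centers[[j]][2L] - max(ro) < 2 ||
              centers[[j]][1L] + max(ro) > d[1L] - 1 ||
              centers[[j]][2L] + max(ro) > d[2L] - 1) { good <- FALSE; break }
        }
        if (!good) next
        m <- annulus_mask(base, d, centers = centers,
                          pert_out = po, pert_in = pi_)
        if (max(EBImage::bwlabel(m)) == n_comp_base) {
          out[[i]] <- m * 1L
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("could not generate a valid training shape after 50 attempts; ",
             "reduce 'radial_amp'", call. = FALSE)
    }
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
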