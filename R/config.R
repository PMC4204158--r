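#' Evolution configuration
#'
#' Collects every tunable of the level-set evolution.  Defaults follow the
#' model's stated choices: curvature weight `rho = 1`, Heaviside width
#' `eps = 1`, shape weight chosen automatically as a fraction of the ratio
#' of the maximum interaction-field magnitude to the maximum shape-flow
#' magnitude at the initial configuration.
#'
#' @param rho Curvature (length-penalty) weight, >= 0.
#' @param nu Shape-prior weight: a nonnegative number, or `"auto"` to apply
#'   the balancing heuristic `nu = nu_fraction * max|G| / max|shape flow|`
#'   at the initial configuration.
#' @param nu_fraction Fraction used by the `"auto"` heuristic, in (0, 1].
#' @param eps Heaviside/Dirac regularization width (pixels).
#' @param dt Time-step cap (pixels); the effective step each iteration is
#'   `min(dt, 0.5 / max|flow|)` (a CFL-like bound).
#' @param band_halfwidth Narrow-band half-width in pixels (>= 2), or `Inf`
#'   for full-domain evolution.
#' @param reinit_every Reinitialize phi to a signed distance function every
#'   this many iterations.
#' @param max_iters Iteration cap.
#' @param tol Convergence threshold on the mean absolute band update per
#'   iteration; evolution stops after 5 consecutive sub-tolerance steps, or
#'   when the foreground mask is unchanged across two consecutive
#'   reinitialization cycles (a locked contour keeps receiving flow that
#'   steepens phi without moving the zero level set, so the update norm
#'   alone can stay above tol at convergence).
#' @param seed Integer seed recorded with the run (the evolution itself is
#'   deterministic; the seed covers any randomized companion steps such as
#'   fixture generation).
#' @param gpf A [gpf_params()] object for the image feature.
#' @return A list of class `"evolution_config"`.
#' @export
evolution_config <- function(rho = 1, nu = "auto", nu_fraction = 0.2,
                             eps = 1, dt = 2, band_halfwidth = 6,
                             reinit_every = 20L, max_iters = 600L,
                             tol = 1e-3, seed = 1L, gpf = gpf_params()) {
  stopifnot(rho >= 0, dt > 0, band_halfwidth >= 2, reinit_every >= 1,
            max_iters >= 1, tol > 0, nu_fraction > 0, nu_fraction <= 1,
            inherits(gpf, "gpf_params"))
  if (!(identical(nu, "auto") || (is.numeric(nu) && length(nu) == 1L && nu >= 0)))
    stop("'nu' must be a nonnegative number or \"auto\"", call. = FALSE)
  stopifnot(eps > 0)
  structure(list(rho = rho, nu = nu, nu_fraction = nu_fraction, eps = eps,
                 dt = dt, band_halfwidth = band_halfwidth,
                 reinit_every = as.integer(reinit_every),
                 max_iters = as.integer(max_iters), tol = tol,
                 seed = as.integer(seed), gpf = gpf),
            class = "evolution_config")
}

#' Read an evolution configuration from YAML
#'
#' Keys mirror the arguments of [evolution_config()]; the `gpf` key holds a
#' nested map with [gpf_params()] arguments.  Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return An `"evolution_config"` object.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  known <- setdiff(names(formals(evolution_config)), "gpf")
  extra <- setdiff(names(y), c(known, "gpf"))
  if (length(extra))
    stop("unknown config keys: ", paste(extra, collapse = ", "), call. = FALSE)
  gp <- y$gpf
  if (!is.null(gp)) {
    extra <- setdiff(names(gp), names(formals(gpf_params)))
    if (length(extra))
      stop("unknown gpf config keys: ", paste(extra, collapse = ", "),
           call. = FALSE)
    y$gpf <- do.call(gpf_params, gp)
  }
  do.call(evolution_config, y)
}

config_as_list <- function(cfg) {
  out <- unclass(cfg)
  out$gpf <- unclass(out$gpf)
  out
}

#' Write a resolved configuration to YAML
#'
#' @param cfg An `"evolution_config"` object (extra resolved fields such as
#'   the numeric auto-nu may be attached as attributes by the caller).
#' @param path Output path.
#' @param extra Named list of resolved values to record alongside (for
#'   provenance, e.g. the numeric value a `"auto"` nu resolved to).
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path, extra = list()) {
  out <- config_as_list(cfg)
  if (length(extra)) out$resolved <- extra
  yaml::write_yaml(out, path)
  invisible(path)
}
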