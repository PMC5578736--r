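#' Semi-infinite surface-source diffusion profile
#'
#' Analytic solution of the diffusion equation for a constant-concentration
#' source held at the surface of a semi-infinite medium:
#' \deqn{C(x, t)/C_0 = \mathrm{erfc}\left(x / 2\sqrt{Dt}\right)}
#' This models tracer held in a sub-pial reservoir penetrating downward
#' into the parenchyma. An optional initial-bolus variant (`source =
#' "bolus"`) uses the half-space Gaussian
#' \eqn{\exp(-x^2/4Dt)} instead, normalized at the surface; the
#' constant-concentration source is the default.
#'
#' Clearance (`params$clearance`) scales the absolute concentration by
#' `exp(-k t)` but leaves the surface-normalized profile unchanged.
#'
#' @param params a [transport_params()].
#' @param t time since application, s (> 0).
#' @param depths depths below the surface, um (>= 0).
#' @param source `"constant"` (default) or `"bolus"`.
#' @return a [spatial_profile()] of kind `"depth"` with attribute
#'   `"absolute_scale"` = exp(-k t).
#' @examples
#' p <- halfspace_profile(transport_params(D = 51), t = 3600,
#'                        depths = seq(0, 1500, by = 1))
#' profile_decay_distance(p, 0.5) # ~409 um
#' @export
halfspace_profile <- function(params, t, depths, source = c("constant", "bolus")) {
  source <- match.arg(source)
  stopifnot(inherits(params, "transport_params"))
  if (!is.numeric(t) || t <= 0) stop("invalid parameter: t must be > 0")
  if (any(depths < 0)) stop("invalid parameter: depths must be >= 0")
  s <- 2 * sqrt(params$D * t)
  rel <- switch(source,
                constant = erfc(depths / s),
                bolus = exp(-(depths / s)^2))
  prof <- spatial_profile(depths, rel, kind = "depth", normalize = FALSE)
  attr(prof, "absolute_scale") <- exp(-params$clearance * t)
  prof
}

#' Fractional-decay distance predicted by the surface-source model
#'
#' Depth at which the relative surface-source profile equals `fraction`,
#' found by bisection on the analytic profile to 1e-3 um (the closed form
#' is \eqn{2\sqrt{Dt}\,\mathrm{erfc}^{-1}(f)}, used to bracket the root).
#' Scales exactly as \eqn{\sqrt{Dt}}.
#'
#' @inheritParams halfspace_profile
#' @param fraction target fraction in (0, 1).
#' @return depth in um.
#' @examples
#' decay_distance(transport_params(D = 51), t = 3600, fraction = 0.5)
#' @export
decay_distance <- function(params, t, fraction = 0.5,
                           source = c("constant", "bolus")) {
  source <- match.arg(source)
  stopifnot(inherits(params, "transport_params"))
  if (!is.numeric(t) || t <= 0) stop("invalid parameter: t must be > 0")
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  s <- 2 * sqrt(params$D * t)
  f <- switch(source,
              constant = function(x) erfc(x / s) - fraction,
              bolus = function(x) exp(-(x / s)^2) - fraction)
  hi <- s
  while (f(hi) > 0) hi <- hi * 2
  lo <- 0
  while (hi - lo > 1e-3) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Point-source (intraparenchymal injection) diffusion profile
#'
#' Free-space Gaussian solution for an instantaneous point release of dose
#' Q: \eqn{C(r,t) = Q (4\pi D t)^{-3/2} \exp(-r^2/4Dt)}. The profile is
#' returned normalized to the value at r = 0; the 10%-decay radius is
#' \eqn{r_{10} = \sqrt{4 D t \ln 10}}.
#'
#' @inheritParams halfspace_profile
#' @param radii radial distances from the injection site, um.
#' @param dose injected amount, arbitrary units (sets the absolute scale
#'   attribute only).
#' @return a [spatial_profile()] of kind `"radial"` with attributes
#'   `"peak_concentration"` (= dose (4 pi D t)^{-3/2} exp(-k t)) and
#'   `"r10"`.
#' @export
point_source_profile <- function(params, t, radii, dose = 1) {
  stopifnot(inherits(params, "transport_params"))
  if (!is.numeric(t) || t <= 0) stop("invalid parameter: t must be > 0")
  if (any(radii < 0)) stop("invalid parameter: radii must be >= 0")
  rel <- exp(-radii^2 / (4 * params$D * t))
  prof <- spatial_profile(radii, rel, kind = "radial", normalize = FALSE)
  attr(prof, "peak_concentration") <-
    dose * (4 * pi * params$D * t)^(-3 / 2) * exp(-params$clearance * t)
  attr(prof, "r10") <- sqrt(4 * params$D * t * log(10))
  prof
}

#' Effective diffusion coefficient in a tortuous medium
#'
#' \eqn{D_{eff} = D_{free} / \lambda^2}: hindrance by the narrow, tortuous
#' extracellular space reduces the free-solution coefficient by the square
#' of the tortuosity.
#'
#' @param D_free free-solution diffusion coefficient (any unit).
#' @param tortuosity dimensionless, >= 1.
#' @return effective coefficient in the same unit as `D_free`.
#' @examples
#' effective_diffusion(6.97, 2.64) # ~1 um^2/s
#' @export
effective_diffusion <- function(D_free, tortuosity) {
  if (any(D_free <= 0)) stop("invalid parameter: D_free must be > 0")
  if (any(tortuosity < 1)) stop("invalid parameter: tortuosity must be >= 1")
  D_free / tortuosity^2
}

#' Relative penetration distances predicted by diffusion alone
#'
#' For tracers diffusing from a common surface source for the same time,
#' every fractional-decay distance scales as \eqn{\sqrt{D}}; the relative
#' predicted penetration of tracer i is therefore
#' \eqn{\sqrt{D_i / D_{max}}}, independent of time and of the chosen
#' fraction.
#'
#' @param tracers a tracer tibble (see [tracer()], [dextran_panel()]) with
#'   `D_ecs` set, or a numeric vector of diffusion coefficients.
#' @param t time, s; kept for interface symmetry (the ratio is
#'   t-independent).
#' @return a tibble with columns `name`, `D_ecs`, `relative_distance`.
#' @examples
#' relative_penetration(c(51, 7.5, 1.0)) # 1, 0.383, 0.140
#' @export
relative_penetration <- function(tracers, t = 3600) {
  if (is.numeric(tracers)) {
    tracers <- tibble::tibble(name = paste0("tracer", seq_along(tracers)),
                              D_ecs = as.numeric(tracers))
  }
  if (nrow(tracers) == 0) stop("at least one tracer is required")
  if (any(!is.finite(tracers$D_ecs)))
    stop("all tracers must have D_ecs set")
  dplyr::mutate(
    tibble::as_tibble(tracers[, intersect(c("name", "D_ecs"), names(tracers))]),
    relative_distance = sqrt(.data$D_ecs / max(.data$D_ecs))
  )
}

#' Scale a profile by extracellular volume fraction
#'
#' Tissue-averaged (absolute) tracer content is the free ECS concentration
#' times the volume fraction alpha; the surface-normalized relative profile
#' is unchanged by alpha alone. Differences in penetration shape between
#' conditions therefore enter only through the effective diffusion
#' coefficient, while alpha rescales total uptake linearly.
#'
#' @param profile a [spatial_profile()].
#' @param alpha extracellular volume fraction in (0, 1], default 0.2.
#' @return the profile with an added `absolute` column
#'   (= alpha * intensity, tissue-averaged uptake relative to the surface
#'   ECS concentration).
#' @export
alpha_adjusted_uptake <- function(profile, alpha = 0.2) {
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  out <- dplyr::mutate(profile, absolute = alpha * .data$intensity)
  class(out) <- class(profile)
  attr(out, "alpha") <- alpha
  out
}
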