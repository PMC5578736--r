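#' Unit conversion between cm^2/s and um^2/s
#'
#' Diffusion coefficients for brain tracers are conventionally reported in
#' cm^2/s; all internal computation uses um and seconds.
#' 1 cm^2/s = 1e8 um^2/s, exactly.
#'
#' @param D numeric vector of diffusion coefficients.
#' @return numeric vector in the target unit.
#' @export
cm2s_to_um2s <- function(D) D * 1e8

#' @rdname cm2s_to_um2s
#' @export
um2s_to_cm2s <- function(D) D / 1e8

#' Transport parameters for solute movement in brain extracellular space
#'
#' Bundles the physical parameters of the convection-diffusion model:
#' effective diffusion coefficient `D` (um^2/s), convective velocity `v`
#' (um/min, converted internally to um/s), tortuosity `lambda` (>= 1), ECS
#' volume fraction `alpha` in (0, 1), and an optional first-order clearance
#' rate `k` (1/s) applied as multiplicative exponential decay.
#'
#' @param D diffusion coefficient, um^2/s (must be > 0).
#' @param v convective velocity, um/min; length-1 (x only) or length-2 (x, y).
#' @param tortuosity dimensionless hindrance factor, >= 1.
#' @param alpha extracellular volume fraction, in (0, 1).
#' @param clearance first-order clearance rate, 1/s, >= 0.
#' @return an object of class `transport_params`.
#' @examples
#' transport_params(D = 51)                   # 10 kDa dextran in vivo
#' transport_params(D = 1, v = c(5, 0))       # with 5 um/min flow along +x
#' @export
transport_params <- function(D, v = c(0, 0), tortuosity = 1, alpha = 0.2,
                             clearance = 0) {
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D <= 0)
    stop("invalid parameter: D must be a single positive number (um^2/s)")
  if (length(v) == 1L) v <- c(v, 0)
  if (length(v) != 2L || any(!is.finite(v)))
    stop("invalid parameter: v must be a finite velocity (um/min), length 1 or 2")
  if (tortuosity < 1) stop("invalid parameter: tortuosity must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("invalid parameter: alpha must lie in (0, 1)")
  if (clearance < 0) stop("invalid parameter: clearance must be >= 0")
  structure(
    list(D = D, v = as.numeric(v), tortuosity = tortuosity, alpha = alpha,
         clearance = clearance),
    class = "transport_params"
  )
}

#' @export
print.transport_params <- function(x, ...) {
  cat("<transport_params>\n")
  cat(sprintf("  D          %g um^2/s (%.3g cm^2/s)\n", x$D, um2s_to_cm2s(x$D)))
  cat(sprintf("  v          (%g, %g) um/min\n", x$v[1], x$v[2]))
  cat(sprintf("  tortuosity %g   alpha %g   clearance %g 1/s\n",
              x$tortuosity, x$alpha, x$clearance))
  invisible(x)
}

# velocity in um/s as used by the simulator
velocity_um_s <- function(params) params$v / 60

#' Define a fluorescent tracer
#'
#' One row per tracer: label, molecular mass (kDa), hydrodynamic radius
#' (nm), free-solution diffusion coefficient and effective coefficient in
#' brain extracellular space (both um^2/s).
#'
#' @param name character label.
#' @param molecular_mass kDa.
#' @param hydrodynamic_radius nm (> 0).
#' @param D_free diffusion coefficient in aqueous solution, um^2/s.
#' @param D_ecs effective diffusion coefficient in brain ECS, um^2/s
#'   (must not exceed `D_free`).
#' @return a one-row tibble of class `tracer_tbl`.
#' @export
tracer <- function(name, molecular_mass = NA_real_,
                   hydrodynamic_radius = NA_real_,
                   D_free = NA_real_, D_ecs = NA_real_) {
  if (!is.na(hydrodynamic_radius) && hydrodynamic_radius <= 0)
    stop("hydrodynamic_radius must be > 0")
  if (!is.na(D_free) && !is.na(D_ecs) && D_ecs > D_free)
    stop("D_ecs cannot exceed D_free")
  out <- tibble::tibble(
    name = as.character(name),
    molecular_mass = molecular_mass,
    hydrodynamic_radius = hydrodynamic_radius,
    D_free = D_free, D_ecs = D_ecs
  )
  class(out) <- c("tracer_tbl", class(out))
  out
}

#' Reference tracer panel
#'
#' The dextran/ovalbumin panel used throughout: in-vivo effective diffusion
#' coefficients of 5.1e-7, 0.75e-7 and 0.1e-7 cm^2/s for the 10, 70 and
#' 2000 kDa dextrans (51, 7.5 and 1.0 um^2/s) and 1.6e-7 cm^2/s (16 um^2/s)
#' for ovalbumin; hydrodynamic radii of roughly 2, 5 and 12 nm for the
#' dextrans. The 2000 kDa coefficient is the free-solution value divided by
#' the square of an assumed tortuosity of 2.64.
#'
#' @return a tibble with one row per tracer.
#' @examples
#' dextran_panel()
#' @export
dextran_panel <- function() {
  dplyr::bind_rows(
    tracer("dextran-10kDa", 10, 2, D_ecs = cm2s_to_um2s(5.1e-7)),
    tracer("dextran-70kDa", 70, 5, D_ecs = cm2s_to_um2s(0.75e-7)),
    tracer("dextran-2000kDa", 2000, 12,
           D_free = cm2s_to_um2s(0.1e-7) * 2.64^2,
           D_ecs = cm2s_to_um2s(0.1e-7)),
    tracer("ovalbumin", 45, 3, D_ecs = cm2s_to_um2s(1.6e-7))
  )
}

#' Read a tracer table from a YAML config
#'
#' Expects a top-level `tracers:` list with fields `name`, `kDa`, `Rh_nm`
#' and `D_cm2s` (converted to um^2/s on read).
#'
#' @param path path to a YAML file.
#' @return a tibble as from [tracer()].
#' @export
read_tracer_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the 'yaml' package")
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$tracers)) stop("config has no 'tracers' entry")
  purrr::map_dfr(cfg$tracers, function(tr) {
    tracer(tr$name, tr$kDa %||% NA_real_, tr$Rh_nm %||% NA_real_,
           D_free = if (is.null(tr$D_free_cm2s)) NA_real_ else cm2s_to_um2s(tr$D_free_cm2s),
           D_ecs = cm2s_to_um2s(tr$D_cm2s))
  })
}
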