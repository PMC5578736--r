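#' Construct a spatial intensity profile
#'
#' A tibble of relative fluorescence versus distance, normalized so the
#' value at distance 0 is 1. `kind` records the geometry the profile was
#' measured in: perpendicular distance from a surface (`depth`), distance
#' from a point source (`radial`), or position along a drawn segment
#' (`line`).
#'
#' @param distance strictly increasing distances in um, starting at 0.
#' @param intensity intensities; normalized to `intensity[1]` unless
#'   `normalize = FALSE`.
#' @param kind one of `"depth"`, `"radial"`, `"line"`.
#' @param normalize divide by the value at distance 0 (default TRUE).
#' @return a tibble of class `spatial_profile` with columns `distance`,
#'   `intensity`, `kind`.
#' @export
spatial_profile <- function(distance, intensity,
                            kind = c("depth", "radial", "line"),
                            normalize = TRUE) {
  kind <- match.arg(kind)
  if (length(distance) != length(intensity))
    stop("distance and intensity must have equal length")
  if (distance[1] != 0) stop("profiles must start at distance 0")
  if (any(diff(distance) <= 0)) stop("distances must be strictly increasing")
  if (normalize) {
    if (!is.finite(intensity[1]) || intensity[1] == 0)
      stop("cannot normalize: intensity at distance 0 is zero or not finite")
    intensity <- intensity / intensity[1]
  }
  out <- tibble::tibble(distance = as.numeric(distance),
                        intensity = as.numeric(intensity),
                        kind = kind)
  class(out) <- c("spatial_profile", class(out))
  out
}

#' Fractional-decay distance of a measured profile
#'
#' Distance at which a (surface-normalized) profile first falls to the given
#' fraction of its value at distance 0, by linear interpolation between the
#' bracketing samples. Returns `NA` when the profile never falls below the
#' fraction (e.g. a flat profile), rather than extrapolating.
#'
#' @param profile a [spatial_profile()] (or any tibble with `distance` and
#'   `intensity` columns).
#' @param fraction target fraction in (0, 1); 0.5 gives the half-distance
#'   d_1/2, 0.1 the 10%-decay distance d_10.
#' @return distance in um, or `NA_real_`.
#' @export
profile_decay_distance <- function(profile, fraction = 0.5) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  x <- profile$distance
  y <- profile$intensity / profile$intensity[1]
  below <- which(y <= fraction)
  if (length(below) == 0) return(NA_real_)
  i <- below[1]
  if (i == 1) return(x[1])
  # linear interpolation on the bracketing segment
  x[i - 1] + (fraction - y[i - 1]) * (x[i] - x[i - 1]) / (y[i] - y[i - 1])
}

#' @export
autoplot.spatial_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$distance, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = switch(object$kind[1],
                 depth = "distance from surface (µm)",
                 radial = "radial distance (µm)",
                 line = "distance along segment (µm)"),
      y = "relative fluorescence"
    ) +
    ggplot2::theme_minimal()
}
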