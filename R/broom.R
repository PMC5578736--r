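#' Tidy and glance methods for comparison objects
#'
#' broom-style accessors: `tidy()` returns the per-group summary table,
#' `glance()` a one-row tibble of test-level statistics.
#'
#' @param x a `halftime_comparison` or `genotype_comparison` object.
#' @param ... unused.
#' @return a tibble.
#' @name tidiers
NULL

#' @export
#' @rdname tidiers
tidy <- function(x, ...) UseMethod("tidy")

#' @export
#' @rdname tidiers
glance <- function(x, ...) UseMethod("glance")

#' @export
tidy.halftime_comparison <- function(x, ...) x$summary

#' @export
glance.halftime_comparison <- function(x, ...) {
  tibble::tibble(n_groups = nrow(x$summary), p_value = x$p_value)
}

#' @export
tidy.genotype_comparison <- function(x, ...) x$summary

#' @export
glance.genotype_comparison <- function(x, ...) {
  tibble::tibble(p_genotype = x$p_genotype, p_position = x$p_position)
}

#' @export
tidy.velocity_bound <- function(x, ...) {
  tibble::tibble(null_velocity_um_min = x$null_displacements)
}

#' @export
glance.velocity_bound <- function(x, ...) {
  tibble::tibble(bound_um_min = x$bound_um_min,
                 n_null = length(x$null_displacements),
                 observed_um_min = x$observed_um_min,
                 directional = x$directional)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
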