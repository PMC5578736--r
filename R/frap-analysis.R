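#' Normalized fluorescence recovery curve and half-time
#'
#' Mean intensity in a circular region of interest per post-bleach frame,
#' normalized as F(t) = (I(t) - I0) / (I_pre - I0), where I_pre is the mean
#' over the pre-bleach frames and I0 the first post-bleach value, so F = 0
#' at the post-bleach floor and F = 1 at the pre-bleach level. The
#' half-recovery time t_1/2 is the earliest time at which F reaches 0.5,
#' linearly interpolated between the bracketing frames; if recovery never
#' reaches 0.5 it is reported as `NA`, not extrapolated.
#'
#' @param stack an [image_stack()] with >= 1 pre-bleach and >= 2 post-bleach
#'   frames.
#' @param roi_center (x, y) in um; `NULL` uses the generator ground truth in
#'   the stack metadata if present, else the image centre.
#' @param roi_diameter region diameter, um.
#' @return a tibble of class `recovery_curve` with columns `time` (s from
#'   bleach) and `F`, and attribute `t_half`.
#' @export
recovery_curve <- function(stack, roi_center = NULL, roi_diameter = 10) {
  stopifnot(inherits(stack, "image_stack"))
  if (stack$prebleach_count < 1 || n_frames(stack) - stack$prebleach_count < 2)
    stop("recovery analysis needs >= 1 pre-bleach and >= 2 post-bleach frames")
  roi_center <- roi_center %||% stack$metadata$center %||%
    (dim(stack$frames)[2:1] * stack$pixel_size / 2)
  mask <- pixel_disk_mask(stack, roi_center, roi_diameter)
  if (!any(mask)) stop("ROI contains no pixels")
  I <- mask_means(stack, mask)
  pre <- seq_len(stack$prebleach_count)
  I_pre <- mean(I[pre])
  I0 <- I[stack$prebleach_count + 1L]
  if (abs(I_pre - I0) <= 1e-9 * max(abs(I_pre), 1))
    stop("degenerate input: no bleach detected (pre-bleach and post-bleach intensities equal)")
  post <- (stack$prebleach_count + 1L):n_frames(stack)
  F <- (I[post] - I0) / (I_pre - I0)
  out <- tibble::tibble(time = stack_times(stack)[post], F = F)
  class(out) <- c("recovery_curve", class(out))
  attr(out, "t_half") <- curve_t_half(out$time, out$F)
  out
}

# earliest time F >= fraction, linear interpolation; NA if never reached
curve_t_half <- function(time, F, fraction = 0.5) {
  hit <- which(F >= fraction)
  if (length(hit) == 0) return(NA_real_)
  i <- hit[1]
  if (i == 1) return(time[1])
  time[i - 1] + (fraction - F[i - 1]) * (time[i] - time[i - 1]) / (F[i] - F[i - 1])
}

#' Half-recovery time of a recovery curve
#'
#' @param curve a [recovery_curve()] (or tibble with `time`, `F`).
#' @param fraction recovery level, default 0.5.
#' @return time in s, or `NA` if the level is never reached.
#' @export
t_half <- function(curve, fraction = 0.5) curve_t_half(curve$time, curve$F, fraction)

#' Quadrant-resolved recovery and asymmetry index
#'
#' Divides the bleached disk into four 90-degree sectors (boundaries
#' aligned to the image axes by default; `rotation` rotates them) and
#' computes one normalized recovery curve per sector. The asymmetry index
#' is the maximum over sector pairs of |t_half_i - t_half_j| divided by the
#' mean sector t_half — 0 for perfectly isotropic recovery.
#'
#' @inheritParams recovery_curve
#' @param rotation sector-boundary rotation, degrees.
#' @return a tibble of class `quadrant_recovery` with columns `quadrant`,
#'   `time`, `F`; attributes `t_half` (per sector) and `asymmetry_index`.
#' @export
quadrant_recovery <- function(stack, roi_center = NULL, roi_diameter = 10,
                              rotation = 0) {
  stopifnot(inherits(stack, "image_stack"))
  roi_center <- roi_center %||% stack$metadata$center %||%
    (dim(stack$frames)[2:1] * stack$pixel_size / 2)
  d <- dim(stack$frames)
  px <- stack$pixel_size
  x <- (seq_len(d[2]) - 0.5) * px
  y <- (seq_len(d[1]) - 0.5) * px
  dx <- matrix(rep(x - roi_center[1], each = d[1]), d[1], d[2])
  dy <- matrix(rep(y - roi_center[2], d[2]), d[1], d[2])
  inside <- dx^2 + dy^2 <= (roi_diameter / 2)^2
  ang <- (atan2(dy, dx) * 180 / pi - rotation) %% 360
  sector <- floor(ang / 90) + 1L # 1..4 counter-clockwise from +x axis
  curves <- purrr::map(1:4, function(q) {
    mask <- inside & sector == q
    if (!any(mask)) stop("empty sector: ROI too small for quadrant analysis")
    I <- mask_means(stack, mask)
    pre <- seq_len(stack$prebleach_count)
    I_pre <- mean(I[pre]); I0 <- I[stack$prebleach_count + 1L]
    if (abs(I_pre - I0) <= 1e-9 * max(abs(I_pre), 1))
      stop("degenerate input: no bleach detected in sector")
    post <- (stack$prebleach_count + 1L):n_frames(stack)
    tibble::tibble(quadrant = q, time = stack_times(stack)[post],
                   F = (I[post] - I0) / (I_pre - I0))
  })
  out <- dplyr::bind_rows(curves)
  th <- vapply(curves, function(cv) curve_t_half(cv$time, cv$F), numeric(1))
  idx <- if (any(is.na(th)) || mean(th) == 0) NA_real_ else
    (max(th) - min(th)) / mean(th)
  class(out) <- c("quadrant_recovery", class(out))
  attr(out, "t_half") <- th
  attr(out, "asymmetry_index") <- idx
  out
}

#' Asymmetry index of a quadrant analysis
#' @param x a [quadrant_recovery()] result.
#' @return dimensionless index (max pairwise t_half difference / mean).
#' @export
asymmetry_index <- function(x) attr(x, "asymmetry_index")

#' Intensity time courses at positions away from the bleach
#'
#' Mean intensity in a small circular window (default 3 um diameter) at
#' each position, for every frame, normalized to the pre-bleach mean at
#' that position. Reveals transient dips as bleached molecules pass by.
#'
#' @inheritParams recovery_curve
#' @param positions list of (x, y) positions in um (or a 2-column matrix).
#' @param window_diameter window size, um.
#' @return a tibble with columns `position` (index), `x`, `y`, `time`,
#'   `intensity`.
#' @export
distal_timecourses <- function(stack, positions, window_diameter = 3) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.matrix(positions)) positions <- asplit(positions, 1)
  d <- dim(stack$frames)
  ext <- d[2:1] * stack$pixel_size
  r <- window_diameter / 2
  purrr::imap_dfr(positions, function(p, i) {
    if (p[1] - r < 0 || p[1] + r > ext[1] || p[2] - r < 0 || p[2] + r > ext[2])
      stop("window clipped by the image border at position ", i)
    mask <- pixel_disk_mask(stack, p, window_diameter)
    I <- mask_means(stack, mask)
    I_pre <- mean(I[seq_len(max(stack$prebleach_count, 1L))])
    tibble::tibble(position = i, x = p[1], y = p[2],
                   time = stack_times(stack), intensity = I / I_pre)
  })
}

#' Group comparison of recovery half-times
#'
#' Routine summary statistics for grouped t_1/2 values: per-group mean and
#' standard error plus a two-sided t-test between the first two groups
#' (Welch). A thin wrapper around `t.test()` by design.
#'
#' @param groups a named list; each element either a numeric vector of
#'   t_1/2 values or a list of recovery curves (t_half extracted).
#' @return an object of class `halftime_comparison` with `summary`
#'   (tibble: group, n, mean, sem) and `p_value`.
#' @export
compare_halftimes <- function(groups) {
  if (length(groups) < 2) stop("at least two groups are required")
  vals <- purrr::map(groups, function(g) {
    if (is.numeric(g)) g else vapply(g, t_half, numeric(1))
  })
  if (any(lengths(vals) < 2)) stop("each group needs >= 2 curves")
  nm <- names(vals) %||% paste0("group", seq_along(vals))
  summ <- tibble::tibble(
    group = nm,
    n = lengths(vals),
    mean = vapply(vals, mean, numeric(1)),
    sem = vapply(vals, function(v) sd(v) / sqrt(length(v)), numeric(1))
  )
  p <- tryCatch(t.test(vals[[1]], vals[[2]])$p.value, error = function(e) NA_real_)
  structure(list(summary = summ, p_value = p, values = vals),
            class = "halftime_comparison")
}

#' @export
print.halftime_comparison <- function(x, ...) {
  cat("<halftime_comparison>\n")
  print(x$summary)
  cat(sprintf("two-sided t-test (first two groups): p = %.3g\n", x$p_value))
  invisible(x)
}

#' Cohen's d from percent change and percent standard deviation
#'
#' Effect size d = percent_change / sd_percent used for a priori power
#' calculations (e.g. a 25% change measured with 10% SD gives d = 2.5).
#'
#' @param percent_change expected change, %.
#' @param sd_percent standard deviation of the measurement, % (> 0).
#' @return dimensionless effect size.
#' @examples
#' effect_size(25, 10) # 2.5
#' @export
effect_size <- function(percent_change, sd_percent) {
  if (any(sd_percent <= 0)) stop("sd_percent must be > 0")
  percent_change / sd_percent
}

#' Rigid pre-registration of a stack to its pre-bleach reference
#'
#' Estimates a per-frame rigid translation against the mean pre-bleach
#' frame (integer-pixel exhaustive search within `max_shift_um`, then
#' quadratic sub-pixel refinement of the sum-of-squared-difference surface)
#' and resamples each frame with bilinear interpolation. Intended for
#' heartbeat-induced jitter.
#'
#' The bleached-spot region carries the directional signal under study, so
#' it can be excluded from the registration objective (`exclude_center` /
#' `exclude_diameter`); by default the bleach geometry recorded in the
#' stack metadata is excluded with a 2x diameter margin. Registration then
#' relies on stationary image structure (tissue heterogeneity).
#'
#' @param stack an [image_stack()].
#' @param max_shift_um search radius, um.
#' @param exclude_center,exclude_diameter circular region (um) excluded
#'   from the registration objective; `NULL` disables the exclusion.
#' @return the registered stack; estimated shifts (um) are stored in
#'   `metadata$registration_shifts`.
#' @export
register_stack <- function(stack, max_shift_um = 3,
                           exclude_center = stack$metadata$center,
                           exclude_diameter = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  if (stack$prebleach_count < 1) stop("registration needs a pre-bleach reference")
  px <- stack$pixel_size
  ref <- apply(stack$frames[, , seq_len(stack$prebleach_count), drop = FALSE],
               c(1, 2), mean)
  w <- max(1L, as.integer(ceiling(max_shift_um / px)))
  d <- dim(stack$frames)
  m <- w + 1L # margin for overlap comparisons
  ri <- (m + 1):(d[1] - m); ci <- (m + 1):(d[2] - m)
  use <- matrix(TRUE, length(ri), length(ci))
  if (!is.null(exclude_center)) {
    exclude_diameter <- exclude_diameter %||%
      (2 * ((stack$metadata$spec %||% list(diameter = 10))$diameter))
    excl <- pixel_disk_mask(stack, exclude_center, exclude_diameter)
    use <- !excl[ri, ci]
    if (!any(use)) stop("exclusion region covers the whole registration window")
  }
  shifts <- matrix(0, n_frames(stack), 2)
  for (t in seq_len(n_frames(stack))) {
    fr <- stack$frames[, , t]
    sse <- matrix(Inf, 2 * w + 1, 2 * w + 1)
    for (dy in -w:w) for (dx in -w:w) {
      diff <- (fr[ri + dy, ci + dx] - ref[ri, ci])[use]
      sse[dy + w + 1, dx + w + 1] <- sum(diff^2)
    }
    best <- arrayInd(which.min(sse), dim(sse))
    sub <- quad_subpixel(-sse, best)
    # d such that frame sampled at p + d matches the reference at p;
    # resampling the frame at p + d realigns it
    d_px <- (c(best[1], best[2]) - (w + 1) + sub) # (dy, dx) in px
    shifts[t, ] <- -d_px * px # frame displacement relative to the reference
    stack$frames[, , t] <- shift_bilinear(fr, d_px[1], d_px[2])
  }
  stack$metadata$registration_shifts <- shifts
  stack
}

# quadratic 1-D sub-pixel offsets from a 3x3 neighbourhood of a maximum of
# `surf` at integer position best = (i, j); returns c(dy, dx) in (-0.5, 0.5)
quad_subpixel <- function(surf, best) {
  i <- best[1]; j <- best[2]
  out <- c(0, 0)
  if (i > 1 && i < nrow(surf)) {
    den <- 2 * (2 * surf[i, j] - surf[i - 1, j] - surf[i + 1, j])
    if (den > 0) out[1] <- (surf[i + 1, j] - surf[i - 1, j]) / den
  }
  if (j > 1 && j < ncol(surf)) {
    den <- 2 * (2 * surf[i, j] - surf[i, j - 1] - surf[i, j + 1])
    if (den > 0) out[2] <- (surf[i, j + 1] - surf[i, j - 1]) / den
  }
  pmin(pmax(out, -0.5), 0.5)
}

# translate a matrix by (dy, dx) pixels with bilinear interpolation,
# replicating edges
shift_bilinear <- function(mat, dy, dx) {
  n <- nrow(mat); m <- ncol(mat)
  yi <- seq_len(n) + dy; xi <- seq_len(m) + dx
  y0 <- pmin(pmax(floor(yi), 1), n); y1 <- pmin(y0 + 1, n)
  x0 <- pmin(pmax(floor(xi), 1), m); x1 <- pmin(x0 + 1, m)
  fy <- pmin(pmax(yi - y0, 0), 1); fx <- pmin(pmax(xi - x0, 0), 1)
  a <- mat[y0, x0, drop = FALSE] * (1 - fy) + mat[y1, x0, drop = FALSE] * fy
  b <- mat[y0, x1, drop = FALSE] * (1 - fy) + mat[y1, x1, drop = FALSE] * fy
  a * rep(1 - fx, each = n) + b * rep(fx, each = n)
}

#' @export
autoplot.recovery_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$F)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "time after bleach (s)", y = "normalized fluorescence") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.quadrant_recovery <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$F,
                                       colour = factor(.data$quadrant))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time after bleach (s)", y = "normalized fluorescence",
                  colour = "quadrant") +
    ggplot2::theme_minimal()
}
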