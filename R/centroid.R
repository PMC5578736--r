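#' Track the bleached-spot centre by a scanning circle
#'
#' For each post-bleach frame, a circle of `scan_diameter` is scanned
#' across the image and the position maximizing the mean decrease of
#' fluorescence from the pre-bleach reference inside the circle is taken as
#' the spot centre. The search runs at pixel resolution and is refined to
#' sub-pixel precision by a quadratic fit to the 3 x 3 neighbourhood of the
#' best grid position. After the first frame the search is restricted to a
#' window of `window_factor` times the scan diameter centred on the
#' previous position, preventing lock-on to noise far away; exact ties are
#' broken toward the smallest displacement from the previous position.
#'
#' @param stack an [image_stack()] with pre-bleach frames (their mean is
#'   the reference).
#' @param scan_diameter circle diameter, um.
#' @param init_center (x, y) um to centre the first-frame search window;
#'   `NULL` searches the whole image.
#' @param window_factor search-window size as a multiple of the scan
#'   diameter.
#' @return a tibble of class `centroid_trace` with columns `time`, `x`,
#'   `y`, `displacement` (um from the first tracked position).
#' @export
track_centroid <- function(stack, scan_diameter = 10, init_center = NULL,
                           window_factor = 2) {
  stopifnot(inherits(stack, "image_stack"))
  if (stack$prebleach_count < 1) stop("a pre-bleach reference frame is required")
  px <- stack$pixel_size
  d <- dim(stack$frames)
  r_px <- scan_diameter / 2 / px
  if (2 * r_px > min(d[1], d[2])) stop("scan circle does not fit in the image")
  ref <- apply(stack$frames[, , seq_len(stack$prebleach_count), drop = FALSE],
               c(1, 2), mean)
  # disk offsets (0-based for the C++ scan)
  rad <- floor(r_px)
  off <- expand.grid(di = -rad:rad, dj = -rad:rad)
  off <- off[off$di^2 + off$dj^2 <= r_px^2, ]
  margin <- rad # candidate centres must keep the disk inside the image
  post <- (stack$prebleach_count + 1L):n_frames(stack)
  times <- stack_times(stack)[post]
  pos <- matrix(NA_real_, length(post), 2)
  prev_px <- NULL # (row, col), 1-based fractional
  win <- ceiling(window_factor * scan_diameter / 2 / px)
  for (k in seq_along(post)) {
    diff <- ref - stack$frames[, , post[k]]
    if (all(abs(diff) < .Machine$double.eps))
      stop("no bleach detected: difference image is identically zero")
    if (is.null(prev_px)) {
      if (!is.null(init_center)) {
        ic <- c(init_center[2], init_center[1]) / px + 0.5 # (row, col)
        rlo <- max(margin + 1, floor(ic[1]) - win)
        rhi <- min(d[1] - margin, ceiling(ic[1]) + win)
        clo <- max(margin + 1, floor(ic[2]) - win)
        chi <- min(d[2] - margin, ceiling(ic[2]) + win)
      } else {
        rlo <- margin + 1; rhi <- d[1] - margin
        clo <- margin + 1; chi <- d[2] - margin
      }
    } else {
      rlo <- max(margin + 1, floor(prev_px[1]) - win)
      rhi <- min(d[1] - margin, ceiling(prev_px[1]) + win)
      clo <- max(margin + 1, floor(prev_px[2]) - win)
      chi <- min(d[2] - margin, ceiling(prev_px[2]) + win)
    }
    surf <- cpp_scan_circle(diff, off$di, off$dj,
                            rlo - 1L, rhi - 1L, clo - 1L, chi - 1L)
    mx <- max(surf)
    cand <- which(surf == mx, arr.ind = TRUE)
    if (nrow(cand) > 1 && !is.null(prev_px)) {
      dd <- (cand[, 1] + rlo - 1 - prev_px[1])^2 +
            (cand[, 2] + clo - 1 - prev_px[2])^2
      cand <- cand[which.min(dd), , drop = FALSE]
    }
    best <- cand[1, ]
    sub <- quad_subpixel(surf, best)
    p_px <- c(best[1] + rlo - 1 + sub[1], best[2] + clo - 1 + sub[2])
    prev_px <- p_px
    pos[k, ] <- c((p_px[2] - 0.5) * px, (p_px[1] - 0.5) * px) # (x, y) um
  }
  out <- tibble::tibble(
    time = times, x = pos[, 1], y = pos[, 2],
    displacement = sqrt((pos[, 1] - pos[1, 1])^2 + (pos[, 2] - pos[1, 2])^2)
  )
  class(out) <- c("centroid_trace", class(out))
  out
}

#' Velocity estimate from a centroid trace
#'
#' Least-squares slope of the tracked position against time, per axis;
#' the speed is the Euclidean norm of the two slopes. More robust to
#' per-frame localization noise than the end-to-end displacement.
#'
#' @param trace a [track_centroid()] result.
#' @return speed in um/min, with attribute `"v"` = (vx, vy) um/min.
#' @export
centroid_velocity <- function(trace) {
  vx <- coef(lm(x ~ time, data = trace))[2] * 60
  vy <- coef(lm(y ~ time, data = trace))[2] * 60
  structure(sqrt(vx^2 + vy^2), v = c(vx, vy))
}

#' Null-calibrated upper bound on convective velocity
#'
#' Calibrates the detection floor of the centroid tracker from
#' zero-velocity (null) simulations at matched noise: the bound is the
#' 95th percentile of the null end-to-end displacements divided by the
#' observation time, expressed in um/min. An observed trace is flagged
#' directional only if its own end-to-end velocity exceeds the bound.
#'
#' @param trace an observed [track_centroid()] trace, or `NULL` for the
#'   bound alone.
#' @param null_traces list of >= 10 null traces (v = 0 simulations at
#'   matched noise).
#' @param probs percentile used for the bound.
#' @return an object of class `velocity_bound`: list with `bound_um_min`,
#'   `null_displacements`, `observed_um_min`, `directional`.
#' @export
velocity_upper_bound <- function(trace = NULL, null_traces, probs = 0.95) {
  if (length(null_traces) < 10)
    stop("at least 10 null traces are required for calibration")
  endd <- function(tr) {
    T <- tr$time[nrow(tr)] - tr$time[1]
    if (T <= 0) stop("observation time must be > 0")
    tr$displacement[nrow(tr)] / T * 60
  }
  nulls <- vapply(null_traces, endd, numeric(1))
  bound <- as.numeric(quantile(nulls, probs))
  obs <- if (is.null(trace)) NA_real_ else endd(trace)
  structure(list(bound_um_min = bound, null_displacements = nulls,
                 observed_um_min = obs,
                 directional = if (is.null(trace)) NA else obs > bound),
            class = "velocity_bound")
}

#' @export
print.velocity_bound <- function(x, ...) {
  cat(sprintf("<velocity_bound> %.3g um/min (95th pct of %d null traces)\n",
              x$bound_um_min, length(x$null_displacements)))
  if (!is.na(x$observed_um_min))
    cat(sprintf("  observed %.3g um/min -> %s\n", x$observed_um_min,
                if (isTRUE(x$directional)) "directional" else "not directional"))
  invisible(x)
}

#' @export
autoplot.centroid_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$displacement)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time after bleach (s)", y = "centroid displacement (µm)") +
    ggplot2::theme_minimal()
}
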