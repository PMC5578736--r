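#' Multi-channel section image
#'
#' Single- or multi-channel 2-D intensity data with physical calibration,
#' as acquired from fixed coronal sections. Channels are named matrices of
#' identical shape; `exposure` records the pixel dwell time per channel
#' variant (us) for exposure bridging.
#'
#' @param channels a named list of numeric matrices (rows = y, columns =
#'   x), or a single matrix.
#' @param pixel_size um per pixel (> 0).
#' @param exposure named numeric vector of dwell times (us), optional.
#' @param mask optional logical matrix outlining the tissue.
#' @param metadata free-form list (ground truth for synthetic images).
#' @return an object of class `section_image`.
#' @export
section_image <- function(channels, pixel_size, exposure = NULL, mask = NULL,
                          metadata = list()) {
  if (is.matrix(channels)) channels <- list(ch1 = channels)
  if (is.null(names(channels)) || any(names(channels) == ""))
    stop("channels must be named")
  dims <- unique(lapply(channels, dim))
  if (length(dims) != 1) stop("all channels must share the same shape")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (!is.null(exposure) && any(exposure <= 0)) stop("exposure must be > 0")
  if (!is.null(mask) && !identical(dim(mask), dims[[1]]))
    stop("mask must match the channel shape")
  structure(list(channels = channels, pixel_size = pixel_size,
                 exposure = exposure, mask = mask, metadata = metadata),
            class = "section_image")
}

get_channel <- function(image, channel) {
  if (is.numeric(channel)) return(image$channels[[channel]])
  if (!channel %in% names(image$channels))
    stop("unknown channel: ", channel)
  image$channels[[channel]]
}

#' Fraction of a region above an intensity threshold
#'
#' (pixels >= threshold within the mask) / (mask pixels). The threshold is
#' an explicit user parameter; `fractional_area_sweep()` repeats the
#' measurement over several thresholds as a robustness check.
#'
#' @param image a [section_image()].
#' @param channel channel name or index.
#' @param threshold intensity threshold.
#' @param mask logical matrix; defaults to the image mask, else the whole
#'   frame.
#' @return fraction in \code{[0, 1]}.
#' @export
fractional_area <- function(image, channel = 1, threshold, mask = NULL) {
  ch <- get_channel(image, channel)
  mask <- mask %||% image$mask %||% matrix(TRUE, nrow(ch), ncol(ch))
  if (!any(mask)) stop("empty mask")
  sum(ch[mask] >= threshold) / sum(mask)
}

#' @rdname fractional_area
#' @param thresholds numeric vector of thresholds.
#' @return for the sweep: a tibble with `threshold` and `fraction`
#'   (nonincreasing in threshold).
#' @export
fractional_area_sweep <- function(image, channel = 1, thresholds, mask = NULL) {
  tibble::tibble(
    threshold = thresholds,
    fraction = vapply(thresholds,
                      function(th) fractional_area(image, channel, th, mask),
                      numeric(1))
  )
}

#' Bridge intensities measured at different exposures
#'
#' Surface intensity measured at a short dwell time (to avoid saturation)
#' is multiplied by the ratio of exposure durations so it can be compared
#' with parenchymal intensity measured at a longer exposure; the detector
#' response is assumed linear in dwell time. Multiplicative, so bridging
#' 1 -> 4 -> 16 us equals bridging 1 -> 16 us directly.
#'
#' @param intensity counts measured at `exposure_short`.
#' @param exposure_short,exposure_long dwell times, us (> 0).
#' @return counts on the long-exposure scale.
#' @examples
#' exposure_bridge(200, 1, 16) # 3200
#' @export
exposure_bridge <- function(intensity, exposure_short, exposure_long) {
  if (any(exposure_short <= 0) || any(exposure_long <= 0))
    stop("exposures must be > 0")
  intensity * exposure_long / exposure_short
}

# Euclidean distance of each pixel centre to a polyline (matrix of (x, y)
# vertices in um) plus the side of the nearest segment: positive where the
# pixel lies to the left of the oriented polyline in image coordinates
# (y increasing downward), i.e. below a surface drawn left-to-right.
polyline_distance <- function(nrow_px, ncol_px, pixel_size, polyline) {
  x <- (seq_len(ncol_px) - 0.5) * pixel_size
  y <- (seq_len(nrow_px) - 0.5) * pixel_size
  PX <- matrix(rep(x, each = nrow_px), nrow_px, ncol_px)
  PY <- matrix(rep(y, ncol_px), nrow_px, ncol_px)
  dmin <- matrix(Inf, nrow_px, ncol_px)
  side <- matrix(1, nrow_px, ncol_px)
  if (is.null(dim(polyline))) polyline <- matrix(polyline, ncol = 2, byrow = TRUE)
  nseg <- max(1, nrow(polyline) - 1)
  for (s in seq_len(nseg)) {
    a <- polyline[min(s, nrow(polyline)), ]
    b <- polyline[min(s + 1, nrow(polyline)), ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      dseg <- sqrt((PX - a[1])^2 + (PY - a[2])^2)
      cross <- matrix(1, nrow_px, ncol_px)
    } else {
      t <- pmin(pmax(((PX - a[1]) * ab[1] + (PY - a[2]) * ab[2]) / len2, 0), 1)
      dseg <- sqrt((PX - (a[1] + t * ab[1]))^2 + (PY - (a[2] + t * ab[2]))^2)
      cross <- ab[1] * (PY - a[2]) - ab[2] * (PX - a[1])
    }
    closer <- dseg < dmin
    side[closer] <- cross[closer]
    dmin <- pmin(dmin, dseg)
  }
  list(distance = dmin, side = side)
}

#' Depth profile of intensity below a surface line
#'
#' Bins pixels by perpendicular (Euclidean) distance from a surface
#' polyline and averages intensity per bin. The profile is normalized to
#' `surface_value` when given (e.g. an exposure-bridged surface intensity),
#' else to its own first bin. The half-penetration distance d_1/2 is read
#' off with [profile_decay_distance()]; it is `NA` when the profile never
#' falls below half.
#'
#' @param image a [section_image()].
#' @param channel channel name or index.
#' @param surface polyline as a matrix of (x, y) vertices in um, oriented
#'   so the tissue lies to its left (below a surface drawn left-to-right,
#'   y increasing downward); a single number is shorthand for a horizontal
#'   surface at that y with depth increasing downward.
#' @param max_depth analyse to this distance, um.
#' @param bin_width bin size, um; defaults to the pixel size.
#' @param surface_value optional reference intensity for normalization.
#' @return a [spatial_profile()] of kind `"depth"`.
#' @export
depth_profile <- function(image, channel = 1, surface, max_depth,
                          bin_width = NULL, surface_value = NULL) {
  ch <- get_channel(image, channel)
  px <- image$pixel_size
  bin_width <- bin_width %||% px
  if (is.numeric(surface) && length(surface) == 1) {
    ext_x <- ncol(ch) * px
    surface <- rbind(c(0, surface), c(ext_x, surface))
    # depth increases downward from a horizontal surface
    y <- (seq_len(nrow(ch)) - 0.5) * px
    dist <- matrix(rep(y - surface[1, 2], ncol(ch)), nrow(ch), ncol(ch))
    keep <- dist >= 0
  } else {
    if (any(surface[, 1] < 0) || any(surface[, 2] < 0) ||
        any(surface[, 1] > ncol(ch) * px) || any(surface[, 2] > nrow(ch) * px))
      stop("surface line lies outside the image")
    pd <- polyline_distance(nrow(ch), ncol(ch), px, surface)
    dist <- pd$distance
    # tissue lies to the left of the oriented polyline (below a surface
    # drawn left-to-right, with y increasing downward)
    keep <- pd$side >= 0
  }
  keep <- keep & dist <= max_depth
  bins <- floor(dist[keep] / bin_width)
  vals <- tapply(ch[keep], bins, mean)
  idx <- as.integer(names(vals))
  dst <- (idx + 0.5) * bin_width
  ord <- order(dst)
  dst <- dst[ord]; vals <- as.numeric(vals)[ord]
  dst <- dst - dst[1] # surface bin at 0
  ref <- surface_value %||% vals[1]
  spatial_profile(dst, vals / ref, kind = "depth", normalize = FALSE)
}

#' Radial profile around an injection site
#'
#' Annulus-mean intensity versus radial distance from a centre point,
#' normalized to the innermost annulus. Annulus width defaults to one
#' pixel. The 10%-decay radius d_10 is read off with
#' [profile_decay_distance()].
#'
#' @param image a [section_image()].
#' @param channel channel name or index.
#' @param center (x, y) in um; must lie within the image.
#' @param max_radius analyse to this radius, um.
#' @param bin_width annulus width, um; defaults to the pixel size.
#' @return a [spatial_profile()] of kind `"radial"`.
#' @export
radial_profile <- function(image, channel = 1, center, max_radius,
                           bin_width = NULL) {
  ch <- get_channel(image, channel)
  px <- image$pixel_size
  bin_width <- bin_width %||% px
  if (center[1] < 0 || center[2] < 0 ||
      center[1] > ncol(ch) * px || center[2] > nrow(ch) * px)
    stop("center lies outside the image")
  x <- (seq_len(ncol(ch)) - 0.5) * px
  y <- (seq_len(nrow(ch)) - 0.5) * px
  r <- sqrt(outer((y - center[2])^2, (x - center[1])^2, `+`))
  keep <- r <= max_radius
  bins <- floor(r[keep] / bin_width)
  vals <- tapply(ch[keep], bins, mean)
  idx <- as.integer(names(vals))
  dst <- (idx + 0.5) * bin_width
  ord <- order(dst)
  dst <- dst[ord] - (idx[ord][1] + 0.5) * bin_width
  spatial_profile(dst, as.numeric(vals)[ord], kind = "radial")
}

#' Intensity profile along a line segment
#'
#' Bilinearly interpolated intensity sampled along a segment (e.g. drawn at
#' right angles to a vessel), normalized to the value at the segment start.
#' The half-distance is read off with [profile_decay_distance()];
#' [average_line_profiles()] averages several vessels onto a common grid as
#' done per animal.
#'
#' @param image a [section_image()].
#' @param channel channel name or index.
#' @param from,to segment endpoints (x, y), um.
#' @param step sampling step, um; defaults to the pixel size.
#' @return a [spatial_profile()] of kind `"line"`.
#' @export
line_profile <- function(image, channel = 1, from, to, step = NULL) {
  ch <- get_channel(image, channel)
  px <- image$pixel_size
  step <- step %||% px
  len <- sqrt(sum((to - from)^2))
  if (len == 0) stop("zero-length segment")
  if (any(c(from, to) < 0) || from[1] > ncol(ch) * px || to[1] > ncol(ch) * px ||
      from[2] > nrow(ch) * px || to[2] > nrow(ch) * px)
    stop("segment lies outside the image")
  s <- seq(0, len, by = step)
  xs <- from[1] + s / len * (to[1] - from[1])
  ys <- from[2] + s / len * (to[2] - from[2])
  vals <- bilinear_sample(ch, xs / px + 0.5, ys / px + 0.5)
  spatial_profile(s, vals, kind = "line")
}

# sample matrix at fractional (col, row) positions (1-based pixel centres)
bilinear_sample <- function(mat, cj, ri) {
  n <- nrow(mat); m <- ncol(mat)
  r0 <- pmin(pmax(floor(ri), 1), n); r1 <- pmin(r0 + 1, n)
  c0 <- pmin(pmax(floor(cj), 1), m); c1 <- pmin(c0 + 1, m)
  fr <- pmin(pmax(ri - r0, 0), 1); fc <- pmin(pmax(cj - c0, 0), 1)
  mat[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    mat[cbind(r1, c0)] * fr * (1 - fc) +
    mat[cbind(r0, c1)] * (1 - fr) * fc +
    mat[cbind(r1, c1)] * fr * fc
}

#' Average several line profiles onto a common grid
#'
#' @param profiles list of [line_profile()] results.
#' @return a [spatial_profile()] of kind `"line"` on the shortest common
#'   distance range.
#' @export
average_line_profiles <- function(profiles) {
  if (length(profiles) == 0) stop("no profiles to average")
  maxd <- min(vapply(profiles, function(p) max(p$distance), numeric(1)))
  grid <- profiles[[1]]$distance[profiles[[1]]$distance <= maxd]
  vals <- rowMeans(vapply(profiles, function(p)
    approx(p$distance, p$intensity, xout = grid)$y, numeric(length(grid))))
  spatial_profile(grid, vals, kind = "line")
}

#' Two-way comparison of per-section measurements between genotypes
#'
#' Routine two-way ANOVA (genotype x section position) on per-section
#' values such as threshold fractional areas, with group means and SEM per
#' position. Group labels can be blinded (hashed) until the final report.
#'
#' @param data a data frame with columns `value`, `genotype`, `position`
#'   (position coerced to factor).
#' @param blind if TRUE, genotype labels are replaced by anonymous codes in
#'   the summary (the ANOVA is label-agnostic).
#' @return an object of class `genotype_comparison` with `summary`,
#'   `p_genotype`, `p_position`, `anova`.
#' @export
genotype_comparison <- function(data, blind = FALSE) {
  stopifnot(all(c("value", "genotype", "position") %in% names(data)))
  data$genotype <- factor(data$genotype)
  data$position <- factor(data$position)
  if (nlevels(data$genotype) < 2) stop("at least two genotype groups are required")
  fit <- aov(value ~ genotype * position, data = data)
  tab <- summary(fit)[[1]]
  rn <- trimws(rownames(tab))
  p_gen <- tab[rn == "genotype", "Pr(>F)"]
  p_pos <- tab[rn == "position", "Pr(>F)"]
  labels <- levels(data$genotype)
  shown <- if (blind) paste0("group-", seq_along(labels)) else labels
  names(shown) <- labels
  summ <- data |>
    dplyr::group_by(.data$genotype, .data$position) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sem = sd(.data$value) / sqrt(dplyr::n()),
                     .groups = "drop") |>
    dplyr::mutate(genotype = shown[as.character(.data$genotype)])
  structure(list(summary = summ, p_genotype = p_gen, p_position = p_pos,
                 anova = fit, blinded = blind),
            class = "genotype_comparison")
}

#' @export
print.genotype_comparison <- function(x, ...) {
  cat("<genotype_comparison> two-way ANOVA\n")
  cat(sprintf("  genotype p = %.3g, position p = %.3g\n",
              x$p_genotype, x$p_position))
  print(x$summary, n = 8)
  invisible(x)
}

#' Display a section image channel
#'
#' @param image a [section_image()].
#' @param channel channel name or index.
#' @return a ggplot raster of the channel.
#' @export
plot_section <- function(image, channel = 1) {
  ch <- get_channel(image, channel)
  px <- image$pixel_size
  # expand_grid varies the last column fastest, matching column-major storage
  df <- tidyr::expand_grid(x = (seq_len(ncol(ch)) - 0.5) * px,
                           y = (seq_len(nrow(ch)) - 0.5) * px)
  df$intensity <- as.vector(ch)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}
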