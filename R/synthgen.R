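#' Acquisition noise model for synthetic microscopy
#'
#' Photon (Poisson) noise with expected `photon_scale` counts per unit
#' concentration, additive Gaussian read noise, and optional per-frame
#' rigid translation jitter emulating heartbeat motion. Identical seeds
#' give identical outputs; `seed = NULL` draws from the session RNG
#' stream.
#'
#' The default photon scale of 100 counts per pixel at unit concentration
#' emulates the signal level of 2-photon time-lapse acquisition at typical
#' detector gain.
#'
#' @param photon_scale expected counts per unit concentration (> 0).
#' @param read_noise_sd Gaussian read noise SD, counts (>= 0).
#' @param jitter_sd per-frame rigid translation SD, um (>= 0).
#' @param seed integer seed, or `NULL`.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(photon_scale = 100, read_noise_sd = 2, jitter_sd = 0,
                        seed = NULL) {
  if (photon_scale <= 0) stop("photon_scale must be > 0")
  if (read_noise_sd < 0) stop("read_noise_sd must be >= 0")
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  structure(list(photon_scale = photon_scale, read_noise_sd = read_noise_sd,
                 jitter_sd = jitter_sd, seed = seed),
            class = "noise_model")
}

# unit-variance Gaussian random field smoothed to the given correlation
# length (px), via separable box smoothing of white noise
smooth_field <- function(ny, nx, scale_px) {
  w <- max(1L, as.integer(round(scale_px)))
  pad <- w
  z <- matrix(rnorm((ny + 2 * pad) * (nx + 2 * pad)), ny + 2 * pad)
  k <- rep(1 / (2 * w + 1), 2 * w + 1)
  z <- apply(z, 2, function(col) stats::filter(col, k, sides = 2))
  z <- t(apply(t(z), 2, function(col) stats::filter(col, k, sides = 2)))
  z <- z[(pad + 1):(pad + ny), (pad + 1):(pad + nx)]
  z[is.na(z)] <- 0
  z / max(sd(as.vector(z)), 1e-12)
}

# noiseless limit: scale only (used by the generators when photon_scale is
# infinite)
apply_noise_matrix <- function(clean, noise) {
  if (!is.finite(noise$photon_scale)) return(clean)
  counts <- matrix(rpois(length(clean), lambda = noise$photon_scale * clean),
                   nrow(clean), ncol(clean))
  if (noise$read_noise_sd > 0)
    counts <- counts + matrix(rnorm(length(clean), 0, noise$read_noise_sd),
                              nrow(clean), ncol(clean))
  counts
}

#' Generate a synthetic FRAP stack with known ground truth
#'
#' Runs the convection-diffusion simulator from a uniform pre-bleach field,
#' samples frames with Poisson photon noise, Gaussian read noise and
#' optional rigid jitter, and prepends noisy pre-bleach frames. Ground
#' truth (all generator parameters) is embedded in the stack metadata.
#'
#' @param params a [transport_params()].
#' @param spec a [bleach_spec()].
#' @param noise a [noise_model()].
#' @param duration recovery time, s.
#' @param frame_interval s per frame.
#' @param grid a [sim_grid()].
#' @param prebleach_frames number of leading pre-bleach frames.
#' @param mode `"2d"` or `"thin3d"` (see [simulate_frap()]).
#' @param background_amplitude amplitude of a static multiplicative
#'   heterogeneity field (smoothed Gaussian random field) emulating tissue
#'   structure; 0 (default) gives a spatially uniform dye distribution.
#'   A nonzero background provides the stationary landmarks that rigid
#'   registration of jittered stacks needs.
#' @param background_scale correlation length of the heterogeneity, um.
#' @return an [image_stack()].
#' @export
make_frap_stack <- function(params, spec = bleach_spec(), noise = noise_model(),
                            duration = 60, frame_interval = 1,
                            grid = sim_grid(), prebleach_frames = 2L,
                            mode = "2d", background_amplitude = 0,
                            background_scale = 5) {
  sim <- simulate_frap(params, spec, duration, frame_interval, grid, mode)
  with_local_seed(noise$seed, {
    d <- dim(sim$frames)
    nt <- prebleach_frames + d[3]
    frames <- array(0, dim = c(d[1], d[2], nt))
    bg <- if (background_amplitude > 0)
      1 + background_amplitude *
        smooth_field(d[1], d[2], background_scale / grid$spacing)
    else matrix(1, d[1], d[2])
    clean_pre <- bg
    for (t in seq_len(nt)) {
      clean <- if (t <= prebleach_frames) clean_pre else
        bg * sim$frames[, , t - prebleach_frames]
      if (noise$jitter_sd > 0) {
        sh <- rnorm(2, 0, noise$jitter_sd) / grid$spacing
        clean <- shift_bilinear(clean, sh[1], sh[2])
      }
      frames[, , t] <- apply_noise_matrix(clean, noise)
    }
    image_stack(frames, pixel_size = grid$spacing,
                frame_interval = frame_interval,
                prebleach_count = prebleach_frames,
                metadata = list(params = params, spec = spec, noise = noise,
                                center = sim$center, mode = mode,
                                truth = list(D = params$D,
                                             v_um_min = params$v,
                                             depth_fraction = spec$depth_fraction,
                                             diameter = spec$diameter)))
  })
}

#' Geometry of a synthetic coronal-section image
#'
#' @param width,height field size, um.
#' @param pixel_size um per pixel.
#' @param surface_y depth (um from the image top) of the parenchymal
#'   surface; pixels above it form the bright surface band.
#' @param band_amplitude surface-band intensity relative to the parenchymal
#'   surface value.
#' @param n_streaks number of paravascular streaks (vertical lines from the
#'   surface, exponential longitudinal decay).
#' @param streak_amplitude streak intensity at the surface, relative units.
#' @param streak_decay streak decay length, um.
#' @param streak_width streak full width, um.
#' @return a list used by [make_section_image()].
#' @export
section_geometry <- function(width = 800, height = 600, pixel_size = 2,
                             surface_y = 30, band_amplitude = 3,
                             n_streaks = 2, streak_amplitude = 1,
                             streak_decay = 150, streak_width = 6) {
  if (width <= 0 || height <= 0 || pixel_size <= 0 || surface_y < 0)
    stop("invalid geometry")
  as.list(environment())
}

#' Generate a synthetic coronal-section image
#'
#' Per tracer channel: a bright surface band, an erfc-shaped parenchymal
#' depth decay given by the surface-source diffusion model
#' ([halfspace_profile()]) for that tracer's `D_ecs` and the stated
#' circulation time, optional paravascular streaks (channel-independent
#' amplitude), and acquisition noise. Ground-truth half-penetration depths
#' are embedded in the metadata.
#'
#' @param tracers a tracer tibble (see [dextran_panel()]).
#' @param t circulation time, s.
#' @param geometry a [section_geometry()].
#' @param noise a [noise_model()].
#' @return a [section_image()].
#' @export
make_section_image <- function(tracers, t = 3600,
                               geometry = section_geometry(),
                               noise = noise_model()) {
  if (nrow(tracers) < 1) stop("at least one tracer is required")
  g <- geometry
  nx <- as.integer(round(g$width / g$pixel_size))
  ny <- as.integer(round(g$height / g$pixel_size))
  y <- (seq_len(ny) - 0.5) * g$pixel_size
  x <- (seq_len(nx) - 0.5) * g$pixel_size
  depth <- y - g$surface_y
  with_local_seed(noise$seed, {
    streak_x <- if (g$n_streaks > 0)
      sort(stats::runif(g$n_streaks, 0.1 * g$width, 0.9 * g$width)) else numeric(0)
    channels <- list(); truth_d <- numeric(0)
    for (i in seq_len(nrow(tracers))) {
      D <- tracers$D_ecs[i]
      prof <- ifelse(depth <= 0, g$band_amplitude,
                     erfc(depth / (2 * sqrt(D * t))))
      img <- matrix(rep(prof, nx), ny, nx)
      for (sx in streak_x) {
        cols <- which(abs(x - sx) <= g$streak_width / 2)
        if (length(cols) > 0) {
          dec <- ifelse(depth > 0,
                        g$streak_amplitude * exp(-depth / g$streak_decay), 0)
          img[, cols] <- img[, cols] + dec
        }
      }
      channels[[tracers$name[i]]] <- apply_noise_matrix(img, noise)
      truth_d[tracers$name[i]] <-
        decay_distance(transport_params(D = D), t, 0.5)
    }
    section_image(channels, pixel_size = g$pixel_size,
                  metadata = list(truth = list(d_half = truth_d, t = t,
                                               D = setNames(tracers$D_ecs, tracers$name),
                                               surface_y = g$surface_y,
                                               streak_x = streak_x),
                                  noise = noise, geometry = g))
  })
}

#' Generate a synthetic intraparenchymal-injection image
#'
#' Per tracer channel: a radial Gaussian spread around the injection site
#' given by the point-source diffusion model, an optional paravascular
#' streak through the site with channel-independent amplitude, and
#' acquisition noise. Ground-truth 10%-decay radii are embedded in the
#' metadata.
#'
#' @param tracers a tracer tibble.
#' @param t time since injection, s.
#' @param center injection site (x, y), um; `NULL` = image centre.
#' @param width,height,pixel_size image geometry, um.
#' @param streak_amplitude streak peak intensity (0 disables the streak).
#' @param streak_decay streak longitudinal decay length, um.
#' @param streak_width streak full width, um.
#' @param noise a [noise_model()].
#' @return a [section_image()].
#' @export
make_injection_image <- function(tracers, t = 3600, center = NULL,
                                 width = 2800, height = 2800, pixel_size = 7,
                                 streak_amplitude = 0, streak_decay = 500,
                                 streak_width = 14,
                                 noise = noise_model()) {
  if (nrow(tracers) < 1) stop("at least one tracer is required")
  nx <- as.integer(round(width / pixel_size))
  ny <- as.integer(round(height / pixel_size))
  center <- center %||% c(width / 2, height / 2)
  x <- (seq_len(nx) - 0.5) * pixel_size
  y <- (seq_len(ny) - 0.5) * pixel_size
  r2 <- outer((y - center[2])^2, (x - center[1])^2, `+`)
  with_local_seed(noise$seed, {
    channels <- list(); truth_r10 <- numeric(0)
    streak <- if (streak_amplitude > 0) {
      # vertical vessel through the injection site
      along <- abs(sweep(matrix(0, ny, nx), 1, y - center[2], `+`))
      across <- abs(sweep(matrix(0, ny, nx), 2, x - center[1], `+`))
      ifelse(across <= streak_width / 2,
             streak_amplitude * exp(-along / streak_decay), 0)
    } else NULL
    for (i in seq_len(nrow(tracers))) {
      D <- tracers$D_ecs[i]
      img <- exp(-r2 / (4 * D * t))
      if (!is.null(streak)) img <- img + streak
      channels[[tracers$name[i]]] <- apply_noise_matrix(img, noise)
      truth_r10[tracers$name[i]] <- sqrt(4 * D * t * log(10))
    }
    section_image(channels, pixel_size = pixel_size,
                  metadata = list(truth = list(r10 = truth_r10, t = t,
                                               center = center,
                                               D = setNames(tracers$D_ecs, tracers$name)),
                                  noise = noise))
  })
}

#' Volume per unit length of a cylindrical capillary
#'
#' pi (d/2)^2 per mm of length, expressed in ul (1 mm^3 = 1 ul); used to
#' read injected volumes off a scored pipette shaft. A 0.86 mm internal
#' diameter gives 0.58 ul/mm, i.e. 0.6 ul at one-decimal precision.
#'
#' @param internal_diameter mm (> 0).
#' @return ul per mm of capillary length.
#' @examples
#' capillary_volume_per_mm(0.86)
#' @export
capillary_volume_per_mm <- function(internal_diameter) {
  if (any(internal_diameter <= 0)) stop("internal_diameter must be > 0")
  pi * (internal_diameter / 2)^2
}

#' Estimate a diffusion coefficient from a FRAP stack
#'
#' Matches the observed half-recovery time against a noiseless reference
#' simulation on the same geometry: diffusive recovery times scale as 1/D,
#' so D_est = D_ref * t_half_ref / t_half_obs.
#'
#' @param stack an [image_stack()] of a FRAP experiment.
#' @param roi_center,roi_diameter analysis region (defaults to the bleach
#'   geometry in the metadata).
#' @param D_ref reference coefficient for the oracle simulation, um^2/s.
#' @param grid simulation grid for the reference; defaults to the stack's
#'   calibration.
#' @return estimated D in um^2/s.
#' @export
estimate_diffusion <- function(stack, roi_center = NULL, roi_diameter = NULL,
                               D_ref = 1, grid = NULL) {
  spec <- stack$metadata$spec %||% bleach_spec()
  roi_diameter <- roi_diameter %||% spec$diameter
  curve <- recovery_curve(stack, roi_center, roi_diameter)
  th_obs <- t_half(curve)
  if (is.na(th_obs)) stop("recovery never reaches half; cannot estimate D")
  d <- dim(stack$frames)
  grid <- grid %||% sim_grid(extent = d[2:1] * stack$pixel_size,
                             spacing = stack$pixel_size)
  fi_ref <- stack$frame_interval
  duration <- 20 * fi_ref
  th_ref <- NA_real_
  for (try in 1:6) { # extend until the reference reaches half recovery
    sim <- simulate_frap(transport_params(D = D_ref), spec,
                         duration = duration, frame_interval = fi_ref,
                         grid = grid, mode = stack$metadata$mode %||% "2d")
    ref_curve <- recovery_curve(sim_to_stack(sim), roi_center, roi_diameter)
    th_ref <- t_half(ref_curve)
    if (!is.na(th_ref)) break
    duration <- duration * 4
  }
  if (is.na(th_ref)) stop("reference simulation did not reach half recovery")
  D_ref * th_ref / th_obs
}
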