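#' Study conditions for the simulated 2-photon FRAP experiments
#'
#' The default parameter set used by the FRAP recipes: a 100 x 100 um field
#' at 0.5 um spacing, a 10 um bleach disk bleached by 50%, 1 s frames for
#' 60 s, photon noise at ~100 counts per pixel, and an effective diffusion
#' coefficient of 0.5 um^2/s. The coefficient is calibrated to the observed
#' in-vivo recovery kinetics of the 500 kDa dextran used for the
#' photobleaching experiments (recovery still clearly incomplete 20 s after
#' bleaching, i.e. a half-recovery time of order 10 s for a 10 um disk);
#' see the methods vignette.
#'
#' @param D effective diffusion coefficient, um^2/s.
#' @param v convective velocity, um/min.
#' @param depth_fraction bleach depth.
#' @param duration,frame_interval acquisition timing, s.
#' @param spacing grid spacing, um.
#' @param photon_scale,read_noise_sd noise levels (see [noise_model()]).
#' @return a list of recipe settings.
#' @export
frap_conditions <- function(D = 0.5, v = c(0, 0), depth_fraction = 0.5,
                            duration = 60, frame_interval = 1, spacing = 0.5,
                            photon_scale = 100, read_noise_sd = 2) {
  list(D = D, v = v, depth_fraction = depth_fraction, duration = duration,
       frame_interval = frame_interval, spacing = spacing,
       photon_scale = photon_scale, read_noise_sd = read_noise_sd)
}

# one seeded FRAP stack under the study conditions
frap_condition_stack <- function(cond, seed, v = cond$v) {
  make_frap_stack(
    transport_params(D = cond$D, v = v),
    bleach_spec(depth_fraction = cond$depth_fraction),
    noise_model(photon_scale = cond$photon_scale,
                read_noise_sd = cond$read_noise_sd, seed = seed),
    duration = cond$duration, frame_interval = cond$frame_interval,
    grid = sim_grid(c(100, 100), cond$spacing)
  )
}

#' Null calibration of the convective-velocity bound
#'
#' Generates `n_seeds` zero-velocity FRAP stacks under the study
#' conditions, tracks the bleach-spot centroid in each, and returns the
#' null-calibrated velocity upper bound (95th percentile of null
#' end-to-end displacement over the observation time).
#'
#' @param n_seeds number of null replicates (>= 10).
#' @param seed base seed; replicate i uses seed + i.
#' @param conditions a [frap_conditions()] list.
#' @return a `velocity_bound` object (see [velocity_upper_bound()]) with
#'   the traces attached as attribute `"traces"`.
#' @export
frap_null_bound <- function(n_seeds = 20, seed = 1,
                            conditions = frap_conditions()) {
  traces <- purrr::map(seq_len(n_seeds), function(i) {
    stack <- frap_condition_stack(conditions, seed + i, v = c(0, 0))
    track_centroid(stack, scan_diameter = 10,
                   init_center = stack$metadata$center)
  })
  out <- velocity_upper_bound(NULL, traces)
  attr(out, "traces") <- traces
  out
}

#' Recover imposed convective velocities from simulated FRAP stacks
#'
#' For each velocity, generates a stack under the study conditions with
#' that flow imposed, tracks the centroid, and estimates the speed from
#' the slope of position against time.
#'
#' @param v_um_min velocities to impose, um/min.
#' @param seed base seed.
#' @param conditions a [frap_conditions()] list.
#' @return a tibble with `v_true`, `v_est` (um/min).
#' @export
frap_velocity_recovery <- function(v_um_min = c(2, 5, 10), seed = 100,
                                   conditions = frap_conditions()) {
  purrr::map_dfr(seq_along(v_um_min), function(i) {
    stack <- frap_condition_stack(conditions, seed + i,
                                  v = c(v_um_min[i], 0))
    tr <- track_centroid(stack, scan_diameter = 10,
                         init_center = stack$metadata$center)
    tibble::tibble(v_true = v_um_min[i],
                   v_est = as.numeric(centroid_velocity(tr)))
  })
}

recipe_registry <- function() c("penetration-prediction", "frap-null",
                                "frap-convection", "arrest-comparison",
                                "genotype-comparison")

#' Run a registered end-to-end experiment recipe
#'
#' Orchestrates simulate -> analyze -> report for the figure-level
#' analyses: `"penetration-prediction"` (relative diffusive penetration of
#' the tracer panel), `"frap-null"` (null-calibrated velocity bound),
#' `"frap-convection"` (velocity recovery under imposed flow),
#' `"arrest-comparison"` (t-test of recovery half-times between equal-D
#' groups and against a 3x slowed group), and `"genotype-comparison"`
#' (two-way ANOVA of threshold fractional areas on matched synthetic
#' sections). Results are written as CSV/JSON into `output_dir` together
#' with a manifest recording the package version, the configuration and an
#' md5 checksum of every output file; given the same seed and parameters
#' the outputs are byte-identical across reruns.
#'
#' @param experiment recipe name.
#' @param params named list overriding recipe defaults.
#' @param seed integer seed for all randomness in the recipe.
#' @param output_dir output directory (created if needed).
#' @return a list with `results` (recipe-specific) and `manifest`,
#'   invisibly; the manifest is also written as `manifest.json`.
#' @export
run_experiment <- function(experiment, params = list(), seed = 1,
                           output_dir = tempfile("frapflow-run-")) {
  if (!experiment %in% recipe_registry())
    stop("unknown experiment '", experiment, "'; registered recipes: ",
         paste(recipe_registry(), collapse = ", "))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  results <- with_local_seed(seed, switch(
    experiment,
    "penetration-prediction" = recipe_penetration(params, output_dir),
    "frap-null" = recipe_frap_null(params, seed, output_dir),
    "frap-convection" = recipe_frap_convection(params, seed, output_dir),
    "arrest-comparison" = recipe_arrest(params, seed, output_dir),
    "genotype-comparison" = recipe_genotype(params, seed, output_dir)
  ))
  files <- setdiff(list.files(output_dir, full.names = TRUE),
                   file.path(output_dir, "manifest.json"))
  manifest <- list(
    package = "frapflow",
    version = as.character(utils::packageVersion("frapflow")),
    experiment = experiment, seed = seed, params = params,
    files = lapply(files, function(f)
      list(name = basename(f), md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(results = results, manifest = manifest,
                 output_dir = output_dir))
}

recipe_penetration <- function(params, out) {
  tracers <- params$tracers %||% dextran_panel()[1:3, ]
  t <- params$t %||% 3600
  fraction <- params$fraction %||% 0.5
  tab <- relative_penetration(tracers, t)
  tab$d_fraction_um <- vapply(tab$D_ecs, function(D)
    decay_distance(transport_params(D = D), t, fraction), numeric(1))
  write.csv(tab, file.path(out, "penetration.csv"), row.names = FALSE)
  tab
}

recipe_frap_null <- function(params, seed, out) {
  cond <- do.call(frap_conditions, params$conditions %||% list())
  n_seeds <- params$n_seeds %||% 20
  vb <- frap_null_bound(n_seeds, seed, cond)
  traces <- attr(vb, "traces")
  tr_tbl <- purrr::imap_dfr(traces, function(tr, i)
    dplyr::mutate(tibble::as_tibble(tr), replicate = i))
  write.csv(tr_tbl, file.path(out, "null_traces.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(velocity_bound_um_min = vb$bound_um_min,
         null_displacement_um_min = vb$null_displacements,
         n_seeds = n_seeds),
    file.path(out, "velocity_bound.json"), auto_unbox = TRUE, digits = NA)
  vb
}

recipe_frap_convection <- function(params, seed, out) {
  cond <- do.call(frap_conditions, params$conditions %||% list())
  v <- params$v_um_min %||% c(2, 5, 10)
  tab <- frap_velocity_recovery(v, seed, cond)
  write.csv(tab, file.path(out, "velocity_recovery.csv"), row.names = FALSE)
  tab
}

# small-field FRAP stack for group comparisons (cheap, half-time oriented)
arrest_stack <- function(D, seed, cond) {
  make_frap_stack(
    transport_params(D = D), bleach_spec(depth_fraction = 0.3),
    noise_model(photon_scale = cond$photon_scale,
                read_noise_sd = cond$read_noise_sd, seed = seed),
    duration = cond$duration, frame_interval = cond$frame_interval,
    grid = sim_grid(c(60, 60), 1)
  )
}

recipe_arrest <- function(params, seed, out) {
  # 150 kDa dextran bleached by ~30%: rapid recovery permitting repeat
  # bleaching; anoxic swelling modelled as a 3x reduction of D
  D_base <- params$D_baseline %||% 1
  D_slow <- params$D_anoxic %||% (D_base / 3)
  n <- params$n_per_group %||% 3
  cond <- list(duration = params$duration %||% 30,
               frame_interval = params$frame_interval %||% 0.5,
               photon_scale = params$photon_scale %||% 100,
               read_noise_sd = params$read_noise_sd %||% 2)
  th <- function(D, s) {
    stack <- arrest_stack(D, s, cond)
    t_half(recovery_curve(stack, roi_diameter = 10))
  }
  g_base <- vapply(seq_len(n), function(i) th(D_base, seed * 1000 + i), numeric(1))
  g_post <- vapply(seq_len(n), function(i) th(D_base, seed * 1000 + 100 + i), numeric(1))
  g_anox <- vapply(seq_len(n), function(i) th(D_slow, seed * 1000 + 200 + i), numeric(1))
  cmp_null <- compare_halftimes(list(baseline = g_base, arrest_1_3min = g_post))
  cmp_anox <- compare_halftimes(list(baseline = g_base, anoxic = g_anox))
  res <- list(t_half = list(baseline = g_base, arrest_1_3min = g_post,
                            anoxic = g_anox),
              p_baseline_vs_arrest = cmp_null$p_value,
              p_baseline_vs_anoxic = cmp_anox$p_value)
  jsonlite::write_json(res, file.path(out, "arrest_comparison.json"),
                       auto_unbox = TRUE, digits = NA)
  res
}

recipe_genotype <- function(params, seed, out) {
  n_mice <- params$n_mice %||% 6
  n_positions <- params$n_positions %||% 5
  threshold <- params$threshold %||% 60
  tracers <- tracer("ovalbumin", 45, 3, D_ecs = 16)
  geom <- do.call(section_geometry, modifyList(
    list(width = 512, height = 384, pixel_size = 4), params$geometry %||% list()))
  rows <- list()
  for (gt in c("wild-type", "knockout")) {
    for (mouse in seq_len(n_mice)) for (pos in seq_len(n_positions)) {
      s <- seed * 10000 + (gt == "knockout") * 5000 + mouse * 100 + pos
      img <- make_section_image(tracers, t = 1800, geometry = geom,
                                noise = noise_model(seed = s))
      rows[[length(rows) + 1]] <- tibble::tibble(
        genotype = gt, mouse = mouse, position = pos,
        value = fractional_area(img, 1, threshold))
    }
  }
  df <- dplyr::bind_rows(rows)
  write.csv(df, file.path(out, "fractional_areas.csv"), row.names = FALSE)
  cmp <- genotype_comparison(df)
  jsonlite::write_json(list(p_genotype = cmp$p_genotype,
                            p_position = cmp$p_position),
                       file.path(out, "genotype_anova.json"),
                       auto_unbox = TRUE, digits = NA)
  cmp
}
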