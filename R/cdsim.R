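#' Define a simulation grid
#'
#' Uniform Cartesian grid over a rectangular field. Cell centres sit at
#' (j - 1/2) * spacing, so a 100 x 100 um field at 0.5 um spacing has
#' 200 x 200 cells symmetric about the field centre. Boundary handling per
#' axis: `"closed"` (zero-flux wall), `"periodic"`, or `"fixed"` (outermost
#' cells pinned at their initial values, i.e. a far-field reservoir —
#' the default, since tissue extends beyond the imaged field).
#'
#' @param extent field size per axis in um, length 1 or 2 (x, y).
#' @param spacing cell size in um (> 0); extent must be a multiple.
#' @param boundary one value or one per axis (x, y).
#' @return an object of class `sim_grid`.
#' @export
sim_grid <- function(extent = c(100, 100), spacing = 0.5,
                     boundary = "fixed") {
  if (length(extent) == 1L) extent <- rep(extent, 2)
  if (spacing <= 0) stop("spacing must be > 0")
  n <- extent / spacing
  if (any(abs(n - round(n)) > 1e-9)) stop("extent must be a multiple of spacing")
  boundary <- match.arg(boundary, c("closed", "periodic", "fixed"),
                        several.ok = TRUE)
  if (length(boundary) == 1L) boundary <- rep(boundary, 2)
  structure(list(extent = extent, spacing = spacing,
                 nx = as.integer(round(n[1])), ny = as.integer(round(n[2])),
                 boundary = boundary),
            class = "sim_grid")
}

boundary_code <- function(b) c(closed = 0L, periodic = 1L, fixed = 2L)[[b]]

#' Concentration field on a grid
#'
#' @param grid a [sim_grid()].
#' @param values scalar or ny x nx matrix of nonnegative concentrations
#'   (rows = y, columns = x).
#' @param time simulation time stamp, s.
#' @return an object of class `concentration_field`.
#' @export
concentration_field <- function(grid, values = 1, time = 0) {
  stopifnot(inherits(grid, "sim_grid"))
  if (is.matrix(values)) {
    if (nrow(values) != grid$ny || ncol(values) != grid$nx)
      stop("values must be a ny x nx matrix")
  } else {
    values <- matrix(values, grid$ny, grid$nx)
  }
  if (any(values < 0)) stop("concentrations must be nonnegative")
  structure(list(grid = grid, values = values, time = time),
            class = "concentration_field")
}

# cell-centre coordinates, um
cell_centers <- function(grid) {
  list(x = (seq_len(grid$nx) - 0.5) * grid$spacing,
       y = (seq_len(grid$ny) - 0.5) * grid$spacing)
}

#' Photobleach specification
#'
#' A circular bleach region: centre (um), diameter (um, default 10),
#' fraction of fluorescence removed inside the disk (default 0.5), and the
#' axial thickness of the bleached slab for the thin-disk 3-D geometry
#' (default 3 um, metadata in 2-D mode).
#'
#' @param center (x, y) in um; `NULL` = field centre at bleach time.
#' @param diameter disk diameter, um (> 0).
#' @param depth_fraction fraction bleached, in (0, 1).
#' @param axial_depth bleached slab thickness, um.
#' @return an object of class `bleach_spec`.
#' @export
bleach_spec <- function(center = NULL, diameter = 10, depth_fraction = 0.5,
                        axial_depth = 3) {
  if (diameter <= 0) stop("diameter must be > 0")
  if (depth_fraction <= 0 || depth_fraction >= 1)
    stop("depth_fraction must lie in (0, 1)")
  structure(list(center = center, diameter = diameter,
                 depth_fraction = depth_fraction, axial_depth = axial_depth),
            class = "bleach_spec")
}

# fractional coverage of each cell by the disk, by 8x8 subsampling;
# gives smooth (anti-aliased) rim weights
disk_coverage <- function(grid, center, diameter) {
  cc <- cell_centers(grid)
  r <- diameter / 2
  sub <- (seq_len(8) - 4.5) / 8 * grid$spacing
  cov <- matrix(0, grid$ny, grid$nx)
  for (dx in sub) for (dy in sub) {
    inside <- outer((cc$y + dy - center[2])^2,
                    (cc$x + dx - center[1])^2, `+`) <= r^2
    cov <- cov + inside
  }
  cov / 64
}

#' Apply a photobleach to a concentration field
#'
#' Multiplies values inside the disk by (1 - depth_fraction), with
#' anti-aliased partial-cell weighting at the rim.
#'
#' @param field a [concentration_field()].
#' @param spec a [bleach_spec()].
#' @return the bleached field.
#' @export
apply_bleach <- function(field, spec) {
  stopifnot(inherits(field, "concentration_field"), inherits(spec, "bleach_spec"))
  grid <- field$grid
  center <- spec$center %||% (grid$extent / 2)
  r <- spec$diameter / 2
  if (center[1] - r < 0 || center[1] + r > grid$extent[1] ||
      center[2] - r < 0 || center[2] + r > grid$extent[2])
    stop("bleach disk lies outside the grid")
  cov <- disk_coverage(grid, center, spec$diameter)
  field$values <- field$values * (1 - spec$depth_fraction * cov)
  field
}

#' Maximal stable explicit time step
#'
#' Stability bound of the forward-time central-space / upwind scheme:
#' `1 / (2 D sum(1/h^2) + sum(|v|/h))` over the active axes.
#'
#' @param grid a [sim_grid()].
#' @param params a [transport_params()].
#' @param mode `"2d"` or `"thin3d"`.
#' @return maximal admissible dt in s.
#' @export
max_stable_dt <- function(grid, params, mode = c("2d", "thin3d")) {
  mode <- match.arg(mode)
  h <- grid$spacing
  v <- abs(velocity_um_s(params))
  ndim <- if (mode == "2d") 2 else 3
  1 / (2 * params$D * ndim / h^2 + sum(v) / h + 1e-300)
}

#' Advance a concentration field one explicit step
#'
#' Flux-form forward-Euler update: central differences for diffusion,
#' first-order upwind for advection. Mass is conserved to round-off with
#' closed or periodic boundaries; nonnegativity is preserved for dt within
#' the stability bound.
#'
#' @inheritParams max_stable_dt
#' @param field a [concentration_field()].
#' @param dt time step, s; must satisfy the stability bound.
#' @return the advanced field.
#' @export
cd_step <- function(field, params, dt) {
  stopifnot(inherits(field, "concentration_field"))
  dt_max <- max_stable_dt(field$grid, params)
  if (dt > dt_max)
    stop(sprintf("dt = %g s violates the stability bound; maximal admissible dt = %g s",
                 dt, dt_max))
  v <- velocity_um_s(params)
  field$values <- cpp_step2d(field$values, params$D, v[1], v[2],
                             field$grid$spacing, dt,
                             boundary_code(field$grid$boundary[2]),
                             boundary_code(field$grid$boundary[1]),
                             params$clearance)
  field$time <- field$time + dt
  field
}

#' Integrate a concentration field over a time span
#'
#' Runs the explicit stepper for `duration` seconds with an automatically
#' chosen stable step (`cfl` times the stability bound, rounded so an
#' integer number of steps covers the span exactly).
#'
#' @inheritParams cd_step
#' @param duration time to integrate, s.
#' @param cfl fraction of the stability bound used for the step.
#' @return the advanced field.
#' @export
cd_run <- function(field, params, duration, cfl = 0.4) {
  stopifnot(inherits(field, "concentration_field"))
  if (duration <= 0) stop("duration must be > 0")
  dt_max <- max_stable_dt(field$grid, params)
  nsteps <- max(1L, as.integer(ceiling(duration / (cfl * dt_max))))
  dt <- duration / nsteps
  v <- velocity_um_s(params)
  arr <- cpp_simulate2d(field$values, params$D, v[1], v[2],
                        field$grid$spacing, dt, nsteps, 1L,
                        boundary_code(field$grid$boundary[2]),
                        boundary_code(field$grid$boundary[1]),
                        params$clearance)
  dim(arr) <- c(field$grid$ny, field$grid$nx, 2L)
  field$values <- arr[, , 2]
  field$time <- field$time + duration
  field
}

#' Simulate fluorescence recovery after photobleaching
#'
#' Starts from a uniform field (concentration 1), applies the bleach, and
#' integrates the convection-diffusion equation, returning frames at the
#' requested cadence with frame 0 immediately post-bleach. In `"thin3d"`
#' mode the field is a 3-D slab of axial extent `axial_extent` with the
#' bleach confined to the central `spec$axial_depth` um and frames read out
#' from the central (focal) plane; `"2d"` is the default.
#'
#' The internal step is chosen automatically at `cfl` (default 0.4) times
#' the stability bound, rounded down so that an integer number of steps
#' fits in each frame interval. The result is deterministic.
#'
#' @inheritParams max_stable_dt
#' @param spec a [bleach_spec()].
#' @param duration recovery time to simulate, s (> 0).
#' @param frame_interval time between output frames, s.
#' @param cfl fraction of the stability bound used for the internal step.
#' @param axial_extent slab thickness in `"thin3d"` mode, um.
#' @return an object of class `frap_sim`: list with `frames`
#'   (ny x nx x n_frames array, frame 1 = post-bleach t = 0), `times`,
#'   `grid`, `params`, `spec`, `mode`.
#' @export
simulate_frap <- function(params, spec = bleach_spec(), duration = 60,
                          frame_interval = 1, grid = sim_grid(),
                          mode = c("2d", "thin3d"), cfl = 0.4,
                          axial_extent = 20) {
  mode <- match.arg(mode)
  if (duration <= 0) stop("duration must be > 0")
  center <- spec$center %||% (grid$extent / 2)
  nframes <- as.integer(round(duration / frame_interval))
  dt_max <- max_stable_dt(grid, params, mode)
  steps_per_frame <- max(1L, as.integer(ceiling(frame_interval / (cfl * dt_max))))
  dt <- frame_interval / steps_per_frame
  v <- velocity_um_s(params)
  bx <- boundary_code(grid$boundary[1]); by <- boundary_code(grid$boundary[2])

  if (mode == "2d") {
    f0 <- apply_bleach(concentration_field(grid, 1), bleach_spec(
      center, spec$diameter, spec$depth_fraction, spec$axial_depth))
    frames <- cpp_simulate2d(f0$values, params$D, v[1], v[2], grid$spacing,
                             dt, steps_per_frame, nframes, by, bx,
                             params$clearance)
  } else {
    p <- as.integer(round(axial_extent / grid$spacing))
    cov <- disk_coverage(grid, center, spec$diameter)
    z <- (seq_len(p) - 0.5) * grid$spacing
    zc <- axial_extent / 2
    slab <- abs(z - zc) <= spec$axial_depth / 2
    field3 <- array(1, dim = c(grid$ny, grid$nx, p))
    for (kk in which(slab))
      field3[, , kk] <- 1 - spec$depth_fraction * cov
    res <- cpp_simulate3d(as.numeric(field3), grid$ny, grid$nx, p,
                          params$D, v[1], v[2], grid$spacing, dt,
                          steps_per_frame, nframes, by, bx,
                          boundary_code("fixed"), params$clearance)
    frames <- res$frames
  }
  dim(frames) <- c(grid$ny, grid$nx, nframes + 1L)
  structure(list(frames = frames,
                 times = seq(0, by = frame_interval, length.out = nframes + 1L),
                 grid = grid, params = params, spec = spec, mode = mode,
                 center = center),
            class = "frap_sim")
}

#' Total mass of a field or simulation frame
#'
#' Sum of concentration times cell area (2-D), um^2 concentration units.
#'
#' @param x a `concentration_field` or a numeric matrix.
#' @param spacing cell size, required when `x` is a bare matrix.
#' @return total mass.
#' @export
total_mass <- function(x, spacing = NULL) {
  if (inherits(x, "concentration_field"))
    return(sum(x$values) * x$grid$spacing^2)
  sum(x) * spacing^2
}
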