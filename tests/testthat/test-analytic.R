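test_that("surface-source profile has erfc shape with correct boundary behaviour", {
  p <- transport_params(D = 51)
  depths <- seq(0, 2000, by = 2)
  prof <- halfspace_profile(p, 3600, depths)
  expect_s3_class(prof, "spatial_profile")
  expect_identical(prof$intensity[1], 1)           # value 1 at the surface
  expect_true(all(diff(prof$intensity) <= 0))      # monotone nonincreasing
  expect_lt(halfspace_profile(p, 3600, c(0, 1e5))$intensity[2], 1e-12) # far field -> 0
  # half-decay depth for the 10 kDa dextran after 60 min: 2 sqrt(Dt) erfcinv(1/2)
  expect_rel_equal(profile_decay_distance(prof, 0.5), 408.72, 1e-3)
  expect_error(halfspace_profile(p, -1, depths), "t must be > 0")
  expect_error(transport_params(D = -5), "D must be")
})

test_that("surface-source profile matches a brute-force finite-difference oracle", {
  D <- 2; t_end <- 400
  fd <- fd_halfspace_oracle(D, t_end, L = 300, h = 0.5)
  ana <- halfspace_profile(transport_params(D = D), t_end, fd$depth)
  rms <- sqrt(mean((ana$intensity - fd$conc)^2))
  expect_lt(rms, 0.01)
})

test_that("decay distance has the closed form and exact sqrt(Dt) scaling", {
  p51 <- transport_params(D = 51)
  expect_rel_equal(decay_distance(p51, 3600, 0.5), 408.72, 1e-3)
  # closed form: 2 sqrt(Dt) erfcinv(f)
  for (f in c(0.1, 0.3, 0.5, 0.8)) {
    closed <- 2 * sqrt(51 * 3600) * (-qnorm(f / 2) / sqrt(2))
    expect_rel_equal(decay_distance(p51, 3600, f), closed, 1e-4)
  }
  # sqrt(D) ratio between the 70 kDa and 10 kDa dextrans
  r <- decay_distance(transport_params(D = 7.5), 3600, 0.5) /
       decay_distance(p51, 3600, 0.5)
  expect_rel_equal(r, sqrt(7.5 / 51), 1e-5)
  # quadrupling t doubles the distance; property sweep over (D, t, f)
  for (D in c(1, 7.5, 51)) for (t in c(600, 3600)) {
    expect_rel_equal(decay_distance(transport_params(D = D), 4 * t, 0.5),
                     2 * decay_distance(transport_params(D = D), t, 0.5), 1e-4)
    f <- c(0.2, 0.4, 0.6, 0.8)
    d <- vapply(f, function(ff) decay_distance(transport_params(D = D), t, ff),
                numeric(1))
    expect_true(all(diff(d) < 0)) # strictly decreasing in fraction
  }
  expect_error(decay_distance(p51, 3600, 1.2), "fraction")
})

test_that("point-source profile is Gaussian with r10 = sqrt(4 D t ln 10)", {
  p <- transport_params(D = 51)
  prof <- point_source_profile(p, 3600, seq(0, 2000, by = 5))
  expect_identical(prof$intensity[1], 1)
  expect_rel_equal(attr(prof, "r10"), 1300.39, 1e-3)
  expect_rel_equal(profile_decay_distance(prof, 0.1), 1300.39, 1e-2)
  # sqrt(t) scaling: 10 min vs 60 min sections
  r10_ratio <- attr(point_source_profile(p, 600, 0), "r10") /
    attr(point_source_profile(p, 3600, 0), "r10")
  expect_rel_equal(r10_ratio, 1 / sqrt(6), 1e-9)
})

test_that("tortuosity reduces mobility quadratically and multiplicatively", {
  expect_equal(effective_diffusion(10, 1), 10)
  expect_equal(effective_diffusion(10, 2), 2.5)
  # inversion of the published estimate for the 2000 kDa dextran
  expect_rel_equal(effective_diffusion(6.97, 2.64), 1.0, 1e-3)
  for (l1 in c(1.2, 2, 2.64)) for (l2 in c(1.1, 1.6)) {
    expect_equal(effective_diffusion(8, l1 * l2),
                 effective_diffusion(effective_diffusion(8, l1), l2))
  }
  expect_error(effective_diffusion(10, 0.9), "tortuosity")
})

test_that("relative penetration follows sqrt(D) ratios, independent of time", {
  out <- relative_penetration(c(51, 7.5, 1.0))
  expect_equal(out$relative_distance, c(1, sqrt(7.5 / 51), sqrt(1 / 51)),
               tolerance = 1e-9)
  expect_equal(round(out$relative_distance, 3), c(1, 0.383, 0.140))
  expect_equal(relative_penetration(5)$relative_distance, 1)
  expect_identical(relative_penetration(c(51, 7.5), t = 600)$relative_distance,
                   relative_penetration(c(51, 7.5), t = 3600)$relative_distance)
  expect_error(relative_penetration(dextran_panel()[0, ]), "at least one")
})

test_that("ECS volume fraction scales uptake linearly, leaves shape alone", {
  p <- halfspace_profile(transport_params(D = 10), 600, seq(0, 300, 1))
  a20 <- alpha_adjusted_uptake(p, 0.2)
  a24 <- alpha_adjusted_uptake(p, 0.24)
  expect_identical(a20$intensity, a24$intensity) # relative profile unchanged
  expect_equal(a24$absolute / a20$absolute, rep(1.2, nrow(p)), tolerance = 1e-12)
  expect_identical(alpha_adjusted_uptake(p, 1)$absolute, p$intensity)
  # a 20% higher D_eff moves d_1/2 by sqrt(1.2)
  d_ratio <- decay_distance(transport_params(D = 12), 600, 0.5) /
    decay_distance(transport_params(D = 10), 600, 0.5)
  expect_rel_equal(d_ratio, sqrt(1.2), 1e-5)
  expect_error(alpha_adjusted_uptake(p, 1.3), "alpha")
})

test_that("unit conversion round-trips to machine precision", {
  D <- c(5.1e-7, 0.75e-7, 0.1e-7, 1.6e-7)
  expect_identical(um2s_to_cm2s(cm2s_to_um2s(D)), D)
  expect_equal(cm2s_to_um2s(5.1e-7), 51)
})

test_that("tracer panel encodes the published coefficients", {
  panel <- dextran_panel()
  expect_equal(panel$D_ecs[panel$name == "dextran-10kDa"], 51)
  expect_equal(panel$D_ecs[panel$name == "dextran-70kDa"], 7.5)
  expect_equal(panel$D_ecs[panel$name == "dextran-2000kDa"], 1)
  expect_equal(panel$D_ecs[panel$name == "ovalbumin"], 16)
  expect_true(all(panel$D_ecs <= panel$D_free, na.rm = TRUE))
  expect_error(tracer("x", D_free = 1, D_ecs = 2), "cannot exceed")
})

test_that("tracer configs read from YAML with unit conversion", {
  skip_if_not_installed("yaml")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("tracers:",
               "  - name: dex10",
               "    kDa: 10",
               "    Rh_nm: 2",
               "    D_cm2s: 5.1e-7"), path)
  tab <- read_tracer_config(path)
  expect_equal(tab$D_ecs, 51)
  expect_equal(tab$molecular_mass, 10)
  shipped <- read_tracer_config(system.file("extdata", "tracers.yaml",
                                            package = "frapflow"))
  expect_equal(shipped$D_ecs, dextran_panel()$D_ecs)
})
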