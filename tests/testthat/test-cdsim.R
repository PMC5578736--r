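test_that("bleach removes the prescribed fraction inside an anti-aliased disk", {
  g <- sim_grid(c(50, 50), 0.5)
  f <- concentration_field(g, 1)
  fb <- apply_bleach(f, bleach_spec(c(25, 25), diameter = 10,
                                    depth_fraction = 0.5))
  cc <- frapflow:::cell_centers(g)
  inner <- outer((cc$y - 25)^2, (cc$x - 25)^2, `+`) <= 4^2 # fully inside
  outer_px <- outer((cc$y - 25)^2, (cc$x - 25)^2, `+`) >= 7^2
  expect_equal(mean(fb$values[inner]), 0.5, tolerance = 1e-12)
  expect_equal(mean(fb$values[outer_px]), 1, tolerance = 1e-12)
  # mass removed = depth_fraction x disk area x pre-bleach level
  removed <- total_mass(f) - total_mass(fb)
  expect_rel_equal(removed, 0.5 * pi * 5^2 * 1, 0.005)
  # ~30% bleach variant
  fb30 <- apply_bleach(f, bleach_spec(c(25, 25), depth_fraction = 0.3))
  expect_equal(mean(fb30$values[inner]), 0.7, tolerance = 1e-12)
  expect_error(apply_bleach(f, bleach_spec(c(2, 2), diameter = 10)),
               "outside the grid")
})

test_that("uniform field is a fixed point and dt above the bound errors", {
  g <- sim_grid(c(30, 30), 1, boundary = "periodic")
  f <- concentration_field(g, 2)
  p <- transport_params(D = 5, v = c(10, 3))
  f2 <- cd_step(f, p, 0.9 * max_stable_dt(g, p))
  expect_equal(f2$values, f$values, tolerance = 1e-13)
  expect_error(cd_step(f, p, 2 * max_stable_dt(g, p)),
               "maximal admissible dt")
})

test_that("delta initial condition relaxes to the analytic Gaussian", {
  g <- sim_grid(c(80, 80), 1, boundary = "closed")
  vals <- matrix(0, 80, 80); vals[40, 40] <- 1
  f <- cd_run(concentration_field(g, vals), transport_params(D = 2), 20)
  cc <- frapflow:::cell_centers(g)
  r2 <- outer((cc$y - cc$y[40])^2, (cc$x - cc$x[40])^2, `+`)
  ana <- exp(-r2 / (4 * 2 * 20))
  num <- f$values / f$values[40, 40]
  keep <- r2 <= 30^2
  expect_lt(sqrt(mean((num[keep] - ana[keep])^2)), 0.01)
})

test_that("fixed-surface simulation reproduces the erfc penetration profile", {
  g <- sim_grid(c(120, 4), 1, boundary = c("fixed", "periodic"))
  vals <- matrix(0, g$ny, g$nx); vals[, 1] <- 1
  f <- cd_run(concentration_field(g, vals), transport_params(D = 2), 100)
  depth <- (seq_len(g$nx) - 1)
  ana <- 2 * pnorm(-sqrt(2) * depth / (2 * sqrt(2 * 100)))
  expect_lt(sqrt(mean((colMeans(f$values) - ana)^2)), 0.01)
})

test_that("pure advection translates a blob at the imposed velocity", {
  g <- sim_grid(c(60, 60), 0.5, boundary = "periodic")
  cc <- frapflow:::cell_centers(g)
  blob <- exp(-outer((cc$y - 30)^2, (cc$x - 20)^2, `+`) / 20)
  # 60 um/min = 1 um/s; D ~ 0 isolates the advection operator
  f <- cd_run(concentration_field(g, blob), transport_params(D = 1e-9, v = c(60, 0)), 1)
  cx0 <- sum(blob %*% cc$x) / sum(blob)
  cx1 <- sum(f$values %*% cc$x) / sum(f$values)
  expect_equal(cx1 - cx0, 1, tolerance = 1e-6)
})

test_that("mass is conserved to round-off with closed and periodic walls", {
  for (b in c("closed", "periodic")) {
    g <- sim_grid(c(50, 50), 1, boundary = b)
    f0 <- apply_bleach(concentration_field(g, 1), bleach_spec(c(25, 25)))
    m0 <- total_mass(f0)
    f1 <- cd_run(f0, transport_params(D = 2, v = c(3, 1)), 60)
    expect_lt(abs(total_mass(f1) - m0) / m0, 1e-6)
    expect_true(all(f1$values >= 0))
  }
})

test_that("advected simulation equals the advected zero-velocity simulation", {
  g <- sim_grid(c(60, 60), 0.5, boundary = "periodic")
  cc <- frapflow:::cell_centers(g)
  blob <- exp(-outer((cc$y - 30)^2, (cc$x - 20)^2, `+`) / 20)
  fa <- cd_run(concentration_field(g, blob), transport_params(D = 2, v = c(60, 0)), 5)
  fb <- cd_run(concentration_field(g, blob), transport_params(D = 2), 5)
  shifted <- fb$values[, c((120 - 9):120, 1:(120 - 10))] # advect by 5 um = 10 cells
  expect_lt(sqrt(mean((fa$values - shifted)^2)) / max(blob), 0.01)
})

test_that("recovery curves converge under grid refinement", {
  curves <- lapply(c(1, 0.5), function(h) {
    st <- quick_sim_stack(D = 1, duration = 20, extent = 60, spacing = h)
    recovery_curve(st, roi_diameter = 10)$F
  })
  expect_lt(sqrt(mean((curves[[1]] - curves[[2]])^2)), 0.01)
})

test_that("thin-disk 3-D mode recovers faster than 2-D at equal D", {
  th2 <- t_half(recovery_curve(quick_sim_stack(D = 0.5, duration = 60)))
  th3 <- t_half(recovery_curve(quick_sim_stack(D = 0.5, duration = 60,
                                               mode = "thin3d")))
  expect_lt(th3, th2)
})

test_that("recovery is monotone toward the plateau and scales as 1/D", {
  st <- quick_sim_stack(D = 1, duration = 30, extent = 60)
  cv <- recovery_curve(st, roi_diameter = 10)
  expect_true(all(diff(cv$F) > -1e-10))
  th1 <- t_half(cv)
  th2 <- t_half(recovery_curve(quick_sim_stack(D = 2, duration = 30, extent = 60),
                               roi_diameter = 10))
  expect_rel_equal(th1 / th2, 2, 0.05) # doubling D halves t_half
})

test_that("exponential clearance drains total mass at rate k", {
  g <- sim_grid(c(30, 30), 1, boundary = "closed")
  f0 <- concentration_field(g, 1)
  f1 <- cd_run(f0, transport_params(D = 1, clearance = 0.02), 50)
  expect_rel_equal(total_mass(f1) / total_mass(f0), exp(-0.02 * 50), 1e-6)
})
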