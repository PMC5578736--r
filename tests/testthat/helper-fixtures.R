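# Shared fixtures: everything is generated in code at test time.

# small, fast FRAP simulation as a noiseless stack
quick_sim_stack <- function(D = 0.5, v = c(0, 0), duration = 40,
                            frame_interval = 1, extent = 100, spacing = 1,
                            diameter = 10, depth_fraction = 0.5,
                            mode = "2d") {
  sim <- simulate_frap(transport_params(D = D, v = v),
                       bleach_spec(diameter = diameter,
                                   depth_fraction = depth_fraction),
                       duration, frame_interval,
                       sim_grid(c(extent, extent), spacing), mode = mode)
  frapflow:::sim_to_stack(sim)
}

# independent brute-force oracle: 1-D explicit finite-difference integration
# of the diffusion equation with a constant-concentration surface node
fd_halfspace_oracle <- function(D, t_end, L = 300, h = 1) {
  n <- as.integer(L / h) + 1L
  c0 <- numeric(n); c0[1] <- 1
  dt <- 0.2 * h^2 / (2 * D)
  nsteps <- ceiling(t_end / dt); dt <- t_end / nsteps
  cc <- c0
  lam <- D * dt / h^2
  for (s in seq_len(nsteps)) {
    lap <- c(0, cc[1:(n - 2)] - 2 * cc[2:(n - 1)] + cc[3:n], 0)
    cc <- cc + lam * lap
    cc[1] <- 1 # constant source
  }
  list(depth = (seq_len(n) - 1) * h, conc = cc)
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / abs(expected), tol)
}
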