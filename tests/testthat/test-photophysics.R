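test_that("photoselection kernel follows the cos^2 law in both geometries", {
  lin <- illumination("switch_on_405", "linear", 2, 1e-6, axis = c(1, 0, 0))
  circ <- illumination("switch_on_405", "circular", 2, 1e-6)
  k <- 50
  expect_equal(excitation_rate_kernel(c(1, 0, 0), lin, k), k * 2)
  expect_equal(excitation_rate_kernel(c(0, 0, 1), lin, k), 0)
  expect_equal(excitation_rate_kernel(c(0, 0, 1), circ, k), 0)
  expect_equal(excitation_rate_kernel(c(0, 1, 0), circ, k), k * 2 / 2)
  u <- sqrt(2) / 2
  expect_equal(excitation_rate_kernel(c(u, u, 0), lin, k), k * 2 * 0.5)
  # smooth in orientation and vectorized
  mu <- cbind(cos(0.3), sin(0.3), 0)
  expect_equal(excitation_rate_kernel(mu, lin, k), k * 2 * cos(0.3)^2)
  expect_error(excitation_rate_kernel(c(1, 1, 0), lin, k), "unit")
  expect_error(illumination("switch_on_405", "linear", 1, 1e-6,
                            axis = c(0, 0, 1)), "perpendicular")
})

test_that("ON-switched fraction saturates and its calibration inverts it", {
  fl <- test_fluor()
  zero <- illumination("switch_on_405", "linear", 0, 250e-9)
  expect_identical(onswitch_fraction(zero, fl), 0)
  huge <- illumination("switch_on_405", "linear", 1e12, 250e-9)
  expect_equal(onswitch_fraction(huge, fl), 1, tolerance = 1e-3)
  # monotone in fluence
  fr <- vapply(10^(1:6), function(p)
    onswitch_fraction(illumination("switch_on_405", "linear", p, 250e-9), fl), 0)
  expect_true(all(diff(fr) > 0))
  for (target in c(0.10, 0.5, 0.9)) {
    pulse <- calibrate_on_power(target, fl)
    expect_equal(onswitch_fraction(pulse, fl), target, tolerance = 1e-8)
  }
  expect_error(onswitch_fraction(illumination("probe_488", "circular",
                                              1, 1e-3), fl), "switch_on_405")
})

test_that("rotational diffusion step is exact on its eigenmodes", {
  g <- test_grid()
  f <- orientation_field(g)
  # D_r = 0 is the identity, the uniform field a fixed point
  expect_identical(propagate_rotation(f, 0, 1)$pop, f$pop)
  prop <- propagate_rotation(f, 1e5, 1e-4)
  expect_equal(prop$pop$OFF, f$pop$OFF, tolerance = 1e-12)
  # a P2 perturbation decays by exp(-6 D dt)
  D <- 1e4; dt <- 2e-5
  f$pop$OFF <- (1 + 0.1 * grid_p2(g)) / (4 * pi)
  out <- propagate_rotation(f, D, dt)
  c2 <- project_p2(g, out$pop$OFF) * 4 * pi
  expect_equal(c2 / 0.1, exp(-6 * D * dt), tolerance = 1e-8)
  # mass conserved, no negative densities
  expect_equal(field_mass(out), field_mass(f), tolerance = 1e-12)
  expect_true(min(out$pop$OFF) > -1e-12)
})

test_that("spectral step matches a brute-force finite-difference propagation", {
  # independent axisymmetric oracle: explicit conservative FD for
  # dn/dt = D d/du [(1-u^2) dn/du] on a cell-centered u grid (the flux
  # factor (1-u^2) vanishes at the poles, closing the scheme)
  D <- 1e4; t_total <- 2e-5
  nu <- 400
  du <- 2 / nu
  u <- -1 + du * (seq_len(nu) - 0.5)
  faces <- -1 + du * (1:(nu - 1))
  n <- 1 + 0.1 * 0.5 * (3 * u^2 - 1)
  dt <- du^2 / (4 * D)
  nstep <- ceiling(t_total / dt)
  dt <- t_total / nstep
  for (s in seq_len(nstep)) {
    flux <- (1 - faces^2) * diff(n) / du
    n <- n + dt * D * c(flux[1], diff(flux), -flux[nu - 1]) / du
  }
  p2 <- 0.5 * (3 * u^2 - 1)
  c2_fd <- sum(du * n * p2) / sum(du * p2^2)
  expect_equal(c2_fd / 0.1, exp(-6 * D * t_total), tolerance = 2e-3)
  # and the engine agrees with the same analytic factor far more tightly
  g <- test_grid()
  f <- orientation_field(g)
  f$pop$OFF <- (1 + 0.1 * grid_p2(g)) / (4 * pi)
  c2_grid <- project_p2(g, propagate_rotation(f, D, t_total)$pop$OFF) * 4 * pi
  expect_equal(c2_grid / 0.1, exp(-6 * D * t_total), tolerance = 1e-4)
})
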