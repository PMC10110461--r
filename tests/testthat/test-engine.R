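test_that("emission geometry reproduces the classical photoselection limits", {
  g <- test_grid()
  fl <- test_fluor()
  rot <- rotor_model(D_r = 0)
  probe <- illumination("probe_488", "circular", 1, 1)
  # fully OFF field: no flux, populations untouched
  f <- orientation_field(g)
  ev <- evolve_populations(f, probe, fl, rot, 1e-9)
  expect_identical(unname(ev$photons), c(0, 0, 0))
  expect_equal(ev$field$pop$OFF, f$pop$OFF, tolerance = 1e-15)
  # isotropic ON population, circular probe: channels balanced, r = 0
  f$pop$ON <- matrix(1 / (4 * pi), g$n_theta, g$n_phi)
  f$pop$OFF[] <- 0
  ev <- evolve_populations(f, probe, fl, rot, 1e-9)
  expect_equal(r_of(ev$photons), 0, tolerance = 1e-12)
  # cos^2-photoselected population, instantaneous probe: r = 0.4
  f$pop$ON <- g$mu_x^2
  ev <- evolve_populations(f, probe, fl, rot, 1e-9)
  expect_equal(r_of(ev$photons), 0.4, tolerance = 1e-10)
})

test_that("emitted anisotropy never exceeds the 0.4 photoselection ceiling", {
  g <- test_grid()
  fl <- test_fluor()
  rot <- rotor_model(D_r = 0)
  probe <- illumination("probe_488", "circular", 1, 1)
  for (a in c(0.01, 0.3, 1, 3, 10, 100)) {
    f <- orientation_field(g)
    f$pop$ON <- 1 - exp(-a * g$mu_x^2)     # saturated photoselection
    f$pop$OFF[] <- 0
    r <- r_of(evolve_populations(f, probe, fl, rot, 1e-9)$photons)
    expect_lte(r, 0.4 + 1e-3)
    expect_gt(r, 0)
  }
})

test_that("an absorption-emission dipole angle depolarizes by P2(cos beta)", {
  g <- test_grid()
  rot <- rotor_model(D_r = 0)
  probe <- illumination("probe_488", "circular", 1, 1)
  r_at <- function(beta) {
    fl <- fluorophore_model(2e3, 12, 2e4, 0.05, dipole_angle_abs_em = beta)
    f <- orientation_field(g)
    f$pop$ON <- g$mu_x^2
    f$pop$OFF[] <- 0
    r_of(evolve_populations(f, probe, fl, rot, 1e-9)$photons[1:2])
  }
  # closed form from uniform-sphere moments for a cos^2_x population probed
  # with circular light: r(beta) = 6 p2 / (14 + p2), p2 = P2(cos beta)
  # (the probe kernel weights the denominator, so the naive 0.4 * P2 is
  # not exact); derived independently by moment algebra
  p2 <- function(b) (3 * cos(b)^2 - 1) / 2
  expect_equal(r_at(0.4), 6 * p2(0.4) / (14 + p2(0.4)), tolerance = 1e-6)
  expect_equal(r_at(0), 0.4, tolerance = 1e-8)
  magic <- acos(1 / sqrt(3))
  expect_equal(r_at(magic), 0, tolerance = 1e-8)
})

test_that("mass is conserved through arbitrary switching sequences", {
  g <- test_grid()
  rot <- rotor_model(tau = 20e-6)
  pulse <- illumination("switch_on_405", "linear", 1e3, 250e-9)
  probe <- illumination("probe_488", "linear", 1e3, 1, axis = c(0, 1, 0))
  for (fl in list(test_fluor(), test_fluor(use_intermediate = TRUE))) {
    f <- orientation_field(g)
    m0 <- field_mass(f)
    for (i in 1:10) f <- evolve_populations(f, pulse, fl, rot, 25e-9)$field
    for (i in 1:20) f <- evolve_populations(f, probe, fl, rot, 5e-6)$field
    expect_equal(field_mass(f), m0, tolerance = 1e-9)
    expect_true(min(vapply(f$pop, min, 0)) > -1e-9)
  }
  # bleaching moves mass into the BLEACHED sink but the total still adds up
  flb <- fluorophore_model(2e3, 12, 2e4, 0.05, bleach_rate = 1e4)
  f <- orientation_field(g, init = "ON")
  for (i in 1:20) f <- evolve_populations(f, probe, flb, rot, 5e-6)$field
  expect_gt(field_mass(f, "BLEACHED"), 0)
  expect_equal(field_mass(f), 1, tolerance = 1e-9)
})

test_that("the ground-state intermediate makes OFF-switching bi-exponential", {
  g <- test_grid()
  rot <- rotor_model(tau = 1e-6)        # fast mixing isolates the kinetics
  probe <- illumination("probe_488", "circular", 2e5, 1)  # high power
  q <- 2e4
  fl <- fluorophore_preset("rsEGFP2", use_intermediate = TRUE)
  expect_equal(fl$intermediate_rate, q)
  f <- orientation_field(g, init = "ON")
  dt <- 1e-6
  traj <- vapply(1:80, function(i) {
    f <<- evolve_populations(f, probe, fl, rot, dt)$field
    c(on = field_mass(f, "ON"), not_off = 1 - field_mass(f, "OFF"))
  }, c(on = 0, not_off = 0))
  ts <- (1:80) * dt
  # fast phase: light-driven ON depletion finishes within a few microseconds
  expect_lt(traj["on", 5], 0.05)
  # ... while most molecules are still waiting in the dark intermediate
  expect_gt(traj["not_off", 5], 0.5)
  # slow phase: completion of OFF-switching at the intermediate's rate
  late <- ts > 2e-5
  slope_late <- coef(lm(log(traj["not_off", late]) ~ ts[late]))[[2]]
  expect_equal(-slope_late, q, tolerance = 0.02)
  # without the intermediate the same probe empties ON essentially at once
  f2 <- orientation_field(g, init = "ON")
  f2$pop$INTERMEDIATE <- NULL
  fl0 <- test_fluor()
  for (i in 1:10) f2 <- evolve_populations(f2, probe, fl0, rot, dt)$field
  expect_lt(1 - field_mass(f2, "OFF"), 0.01)
})

test_that("405-nm light drives only the OFF-to-ON transition", {
  g <- test_grid()
  fl <- test_fluor()
  rot <- rotor_model(D_r = 0)
  pulse <- illumination("switch_on_405", "linear", 1e6, 250e-9)
  f <- orientation_field(g, init = "ON")
  ev <- evolve_populations(f, pulse, fl, rot, 250e-9)
  expect_equal(ev$field$pop$ON, f$pop$ON, tolerance = 1e-15)
  expect_identical(unname(ev$photons), c(0, 0, 0))  # no emission under 405
})

test_that("sphere-grid engine matches the independent Legendre-mode oracle", {
  fl <- test_fluor()
  D <- 1 / (6 * 30e-6)
  nb <- 20; bw <- 2e-5
  oracle <- legendre_oracle_photons(fl, 1e3, D, 0.3, nb, bw)
  engine <- grid_engine_photons(fl, 1e3, D, 0.3, nb, bw)
  expect_lt(max(abs(engine / oracle - 1)), 1e-3)
  # and a pure-diffusion-free variant (D = 0)
  oracle0 <- legendre_oracle_photons(fl, 1e3, 0, 0.3, nb, bw)
  engine0 <- grid_engine_photons(fl, 1e3, 0, 0.3, nb, bw)
  expect_lt(max(abs(engine0 / oracle0 - 1)), 1e-3)
})
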