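test_that("the anisotropy estimator reproduces direct arithmetic", {
  cur <- decay_curve(c(1, 2, 3) * 1e-6, c(100, 300, 120), c(100, 100, 60),
                     1e-6)
  # isotropic, strongly polarized, and a corrected case with G and bg
  an <- compute_anisotropy(cur)
  expect_equal(an$r[1], 0)
  expect_equal(an$r[2], 0.4)
  an2 <- compute_anisotropy(cur, G = 2, background = c(20, 20))
  expect_equal(an2$r[3], (100 - 80) / (100 + 160))
})

test_that("bins with a non-positive corrected denominator are flagged, not dropped", {
  cur <- decay_curve(c(1, 2) * 1e-6, c(10, 0), c(10, 0), 1e-6)
  an <- compute_anisotropy(cur, background = c(10, 10))
  expect_length(an$r, 2)
  expect_false(any(an$valid))
  expect_true(all(is.na(an$r)))          # flagged NA, no NaN propagation
  # and a background-only record subtracted to zero behaves the same
  bgonly <- decay_curve(c(1, 2) * 1e-6, c(50, 50), c(50, 50), 1e-6)
  an2 <- compute_anisotropy(bgonly, background = c(50, 50))
  expect_false(any(an2$valid))
})

test_that("delta-method intervals shrink as 1/sqrt(N) and match the bootstrap", {
  t <- 1e-6
  a1 <- compute_anisotropy(decay_curve(t, 300, 100, 1e-6))
  a2 <- compute_anisotropy(decay_curve(t, 30000, 10000, 1e-6))
  w1 <- a1$ci95_hi - a1$ci95_lo
  w2 <- a2$ci95_hi - a2$ci95_lo
  expect_equal(w1 / w2, 10, tolerance = 1e-10)
  # symmetric channels at G = 1: interval symmetric about r = 0
  s <- compute_anisotropy(decay_curve(t, 500, 500, 1e-6))
  expect_equal(s$ci95_hi, -s$ci95_lo, tolerance = 1e-12)
  # bootstrap agreement within 15% of interval width for counts >= 100
  b <- compute_anisotropy(decay_curve(t, 300, 100, 1e-6), ci = "bootstrap",
                          B = 1000, seed = 1)
  wb <- b$ci95_hi - b$ci95_lo
  expect_equal(unname(wb / w1), 1, tolerance = 0.15)
  # zero-count bins: undefined interval
  z <- compute_anisotropy(decay_curve(t, 0, 0, 1e-6))
  expect_true(is.na(z$ci95_lo) && is.na(z$ci95_hi))
})

test_that("G calibration recovers the gain ratio and r = 0 on the calibration record", {
  fl <- test_fluor(); g <- test_grid()
  # deterministic gains
  flat <- decay_curve((1:20) * 1e-5, rep(200, 20), rep(100, 20), 1e-5)
  expect_equal(calibrate_g(flat), 2)
  flat1 <- decay_curve((1:20) * 1e-5, rep(150, 20), rep(150, 20), 1e-5)
  expect_equal(calibrate_g(flat1), 1)
  # Poisson record with true G = 1.3 and ~1e6 counts: within 1%
  cal <- simulate_calibration_record(fl, detector_pair(g_factor = 1.3),
                                     grid = g, seed = 11,
                                     target_photons = 1e6)
  Ghat <- calibrate_g(cal)
  expect_equal(Ghat, 1.3, tolerance = 0.01)
  an <- compute_anisotropy(cal, G = Ghat)
  m <- mean(an$r[an$valid])
  expect_lt(abs(m), 3 * 1.5 / sqrt(sum(an$counts_parallel)))
  # an anisotropic (time-trending) calibration sample raises a warning
  trend <- simulate_method2(fl, rotor_model(D_r = 0), grid = g,
                            bin_width = 2e-5, reset = FALSE,
                            probe_488 = illumination("probe_488", "linear",
                                                     1e3, 5e-4,
                                                     axis = c(1, 0, 0)))
  expect_warning(calibrate_g(trend), "anisotropic")
})

test_that("gain and background corrections are exact inverses", {
  # gain invariance: scaling the perpendicular channel by c and the
  # calibrated G identically leaves r unchanged
  t <- (1:10) * 1e-6
  cnt <- counts_from_r(0.25 * exp(-t / 5e-6), 1e4)
  r0 <- compute_anisotropy(decay_curve(t, cnt$par, cnt$perp, 1e-6))$r
  for (cc in c(0.5, 2, 3.7)) {
    rc <- compute_anisotropy(decay_curve(t, cnt$par, cnt$perp / cc, 1e-6),
                             G = cc)$r
    expect_equal(rc, r0, tolerance = 1e-12)
  }
  # adding equal constant background to both channels and subtracting the
  # estimate restores r exactly (G = 1)
  rb <- compute_anisotropy(decay_curve(t, cnt$par + 40, cnt$perp + 40, 1e-6),
                           background = c(40, 40))$r
  expect_equal(rb, r0, tolerance = 1e-12)
})
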