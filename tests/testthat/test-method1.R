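test_that("seeded method-1 simulations are bit-reproducible", {
  fl <- test_fluor(); g <- test_grid()
  rot <- rotor_model(tau = 30e-6)
  args <- list(fl, rot, grid = g, bin_width = 2e-5, seed = 7,
               target_photons = 1e5,
               probe_488 = illumination("probe_488", "circular", 1e3, 4e-4))
  a <- do.call(simulate_method1, args)
  b <- do.call(simulate_method1, args)
  expect_identical(a$counts_parallel, b$counts_parallel)
  expect_identical(a$counts_perpendicular, b$counts_perpendicular)
  args$seed <- 8
  c3 <- do.call(simulate_method1, args)
  expect_false(identical(a$counts_parallel, c3$counts_parallel))
})

test_that("detected photons scale linearly with cycles and brightness", {
  fl <- test_fluor(); g <- test_grid()
  rot <- rotor_model(tau = 30e-6)
  probe <- illumination("probe_488", "circular", 1e3, 4e-4)
  base <- simulate_method1(fl, rot, grid = g, bin_width = 2e-5,
                           probe_488 = probe)
  tot <- function(cur) sum(cur$counts_parallel + cur$counts_perpendicular)
  thrice <- simulate_method1(fl, rot, grid = g, bin_width = 2e-5,
                             probe_488 = probe, cycles = 3)
  expect_equal(tot(thrice), 3 * tot(base), tolerance = 1e-12)
  fl2 <- fluorophore_model(fl$k_on_peak, fl$k_off_peak, fl$k_exc_peak,
                           2 * fl$brightness)
  bright <- simulate_method1(fl2, rot, grid = g, bin_width = 2e-5,
                             probe_488 = probe)
  expect_equal(tot(bright), 2 * tot(base), tolerance = 1e-12)
})

test_that("noiseless free-rotor anisotropy decays with the rotor's tau", {
  fl <- test_fluor(); g <- test_grid()
  tau <- 100e-6
  cur <- simulate_method1(fl, rotor_model(tau = tau), grid = g,
                          bin_width = 2e-6, target_photons = 1e7)
  an <- compute_anisotropy(cur, use_segments = "probe")
  fit <- fit_monoexponential(an)
  expect_false(fit$tau_unconstrained)
  expect_equal(fit$tau, tau, tolerance = 0.05)
})

test_that("fast and static rotors bracket the anisotropy decay", {
  fl <- test_fluor(); g <- test_grid()
  probe <- illumination("probe_488", "circular", 1e3, 1e-3)
  # rotor much faster than the binning: r ~ 0 everywhere
  fast <- simulate_method1(fl, rotor_model(tau = 1e-9), grid = g,
                           bin_width = 2e-5, probe_488 = probe,
                           target_photons = 1e6)
  rf <- compute_anisotropy(fast, use_segments = "probe")
  expect_true(all(abs(rf$r[rf$valid]) < 0.01))
  # static rotor: flat curve, drift below 0.02 over the probe window
  stat <- simulate_method1(fl, rotor_model(D_r = 0), grid = g,
                           bin_width = 2e-5, probe_488 = probe,
                           target_photons = 1e6)
  rs <- compute_anisotropy(stat, use_segments = "probe")
  expect_lt(diff(range(rs$r[rs$valid])), 0.02)
  expect_gt(mean(rs$r[rs$valid]), 0.3)    # still strongly anisotropic
})

test_that("sampled counts are Poisson draws around the expectation", {
  fl <- test_fluor(); g <- test_grid()
  rot <- rotor_model(tau = 30e-6)
  probe <- illumination("probe_488", "circular", 1e3, 4e-4)
  mu <- simulate_method1(fl, rot, grid = g, bin_width = 2e-5,
                         probe_488 = probe, target_photons = 2e6,
                         reset = FALSE)
  # mean of many bin-level draws matches the expectation within 3 SE
  expect_bins <- mu$counts_parallel
  draws <- with(list(), {
    set.seed(42)
    matrix(rpois(500 * length(expect_bins), rep(expect_bins, each = 500)),
           nrow = 500)
  })
  se <- sqrt(expect_bins / 500)
  expect_true(all(abs(colMeans(draws) - expect_bins) < 3 * se + 1e-9))
  # the simulator's own sampled output has Poisson-scale residuals
  samp <- simulate_method1(fl, rot, grid = g, bin_width = 2e-5,
                           probe_488 = probe, target_photons = 2e6,
                           reset = FALSE, seed = 3)
  z <- (samp$counts_parallel - expect_bins) / sqrt(expect_bins)
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)) + 0.2)
  expect_lt(sd(z), 1.5)
})

test_that("undersampled decays raise a warning", {
  fl <- test_fluor(); g <- test_grid()
  expect_warning(
    simulate_method1(fl, rotor_model(tau = 30e-6), grid = g,
                     bin_width = 5e-4,
                     probe_488 = illumination("probe_488", "circular",
                                              1e6, 5e-4),
                     reset = FALSE),
    "undersampled")
})

test_that("background is estimated from the reset window and subtracts out", {
  fl <- test_fluor(); g <- test_grid()
  rot <- rotor_model(tau = 30e-6)
  det <- detector_pair(background_rate = 2e5)
  cur <- simulate_method1(fl, rot, detector = det, grid = g,
                          bin_width = 2e-5, target_photons = 1e6)
  bg <- estimate_background(cur)
  expect_equal(unname(bg$rate), c(2e5, 2e5), tolerance = 0.02)
  # zero-background record: estimate is negligible against the signal
  cur0 <- simulate_method1(fl, rot, grid = g, bin_width = 2e-5,
                           target_photons = 1e6)
  bg0 <- estimate_background(cur0)
  peak <- max(cur0$counts_parallel / cur0$bin_width)
  expect_true(all(bg0$rate < 1e-6 * peak))
  # no reset window: instructive error
  nor <- simulate_method1(fl, rot, grid = g, bin_width = 2e-5, reset = FALSE)
  expect_error(estimate_background(nor), "reset")
  # subtracting the estimate from an expectation record restores r
  an_raw <- compute_anisotropy(cur0, use_segments = "probe")
  an_bgd <- compute_anisotropy(cur, background = bg, use_segments = "probe")
  expect_equal(an_bgd$r[an_bgd$valid][1:10], an_raw$r[an_raw$valid][1:10],
               tolerance = 1e-4)
})
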