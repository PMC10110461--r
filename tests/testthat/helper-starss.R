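# shared fixtures: a modest sphere grid keeps the engine fast while the
# spectral propagator stays exact to the band limit
test_grid <- function() sphere_grid(32, 64)
test_fluor <- function(...) fluorophore_preset("rsEGFP2", ...)
test_env <- function() environment_params()

# P2(cos theta) on the grid's polar coordinate
grid_p2 <- function(grid) 0.5 * (3 * grid$mu_z^2 - 1)

# project a (theta, phi) field onto P2(cos theta)
project_p2 <- function(grid, f) {
  sphere_integral(grid, f * grid_p2(grid)) / (4 * pi / 5)
}

# anisotropy of a photon pair
r_of <- function(photons) {
  unname((photons[1] - photons[2]) / (photons[1] + 2 * photons[2]))
}

# independent Legendre-mode oracle for an axially symmetric OFF-switching
# problem: ON density n(u, t) expanded in Legendre polynomials, circular
# 488-nm kernel (1 - u^2)/2 coupling l -> l +/- 2 through multiplication
# by u^2, diffusion damping l(l+1) D. Integrates the mode ODEs (deSolve)
# together with the cumulative emitted photons, so per-bin photon counts
# are exact to the ODE tolerance. Fully independent of the sphere-grid
# engine.
legendre_oracle_photons <- function(fluor, power, D_r, a2_rel, n_bins,
                                    bin_width, l_max = 20) {
  ls <- 0:l_max
  # matrix of multiplication by u^2 in the Legendre basis:
  # x P_l = ((l+1) P_{l+1} + l P_{l-1}) / (2l + 1), applied twice
  M <- matrix(0, l_max + 1, l_max + 1)
  step_x <- function(l) c(up = (l + 1) / (2 * l + 1), dn = l / (2 * l + 1))
  for (j in ls) {
    c1 <- step_x(j)
    terms <- list()
    if (j + 1 <= l_max + 1) terms <- c(terms, list(c(j + 1, c1[["up"]])))
    if (j - 1 >= 0) terms <- c(terms, list(c(j - 1, c1[["dn"]])))
    for (tm in terms) {
      l2 <- tm[1]; w2 <- tm[2]
      c2 <- step_x(l2)
      if (l2 + 1 <= l_max) M[l2 + 2, j + 1] <- M[l2 + 2, j + 1] + w2 * c2[["up"]]
      if (l2 - 1 >= 0) M[l2, j + 1] <- M[l2, j + 1] + w2 * c2[["dn"]]
    }
  }
  k_off <- fluor$k_off_peak * power
  k_exc <- fluor$k_exc_peak * power
  K <- k_off * (diag(l_max + 1) - M) / 2
  Ld <- diag(ls * (ls + 1) * D_r)
  # total flux = brightness k_exc 0.75 int n (1-u^2)^2 dOmega with
  # (1-u^2)^2 = 8/15 P0 - 16/21 P2 + 8/35 P4 and int P_l^2 du = 2/(2l+1)
  flux_of <- function(a)
    fluor$brightness * k_exc * 0.75 * 2 * pi *
      (8 / 15 * a[1] * 2 + (-16 / 21) * a[3] * 2 / 5 + 8 / 35 * a[5] * 2 / 9)
  a0 <- rep(0, l_max + 1)
  a0[1] <- 1 / (4 * pi)
  a0[3] <- a2_rel / (4 * pi)
  rhs <- function(t, y, p) {
    a <- y[seq_len(l_max + 1)]
    list(c(-(K + Ld) %*% a, flux_of(a)))
  }
  sol <- deSolve::ode(c(a0, 0), seq(0, n_bins * bin_width, by = bin_width),
                      rhs, NULL, rtol = 1e-10, atol = 1e-14)
  diff(sol[, l_max + 3])
}

# the same problem on the sphere-grid engine
grid_engine_photons <- function(fluor, power, D_r, a2_rel, n_bins,
                                bin_width, grid = test_grid(), n_sub = 10) {
  probe <- illumination("probe_488", "circular", power, 1)
  field <- orientation_field(grid, init = "ON")
  field$pop$ON <- (1 + a2_rel * grid_p2(grid)) / (4 * pi)
  rot <- rotor_model(D_r = max(D_r, 1e-30))
  rot$D_r <- D_r
  photons <- numeric(n_bins)
  for (b in seq_len(n_bins)) {
    acc <- 0
    for (i in seq_len(n_sub)) {
      ev <- evolve_populations(field, probe, fluor, rot, bin_width / n_sub)
      field <- ev$field
      acc <- acc + ev$photons[["parallel"]] + ev$photons[["perpendicular"]]
    }
    photons[b] <- acc
  }
  photons
}

# build Poisson channel counts for a prescribed anisotropy profile
counts_from_r <- function(r, total_per_bin, seed = NULL) {
  mu_par <- total_per_bin * (1 + 2 * r) / 3
  mu_perp <- total_per_bin * (1 - r) / 3
  if (!is.null(seed)) {
    set.seed(seed)
    mu_par <- rpois(length(mu_par), mu_par)
    mu_perp <- rpois(length(mu_perp), mu_perp)
  }
  list(par = mu_par, perp = mu_perp)
}

# wrap channel counts into an anisotropy curve via the standard path
aniso_from_counts <- function(t, cnt, bin_width = diff(t)[1]) {
  cur <- decay_curve(t, cnt$par, cnt$perp, bin_width)
  compute_anisotropy(cur)
}
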