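# (1 - exp(-k dt)) / k with the k -> 0 limit handled; vectorized over k
.em1 <- function(k, dt) ifelse(k > 0, -expm1(-k * dt) / pmax(k, .Machine$double.xmin), dt)

# polarization-resolved detection weights for the two analyzers (x, y).
# Point-dipole emission projected on the analyzers, azimuthally averaged
# over the abs->em dipole cone of half-angle beta; normalized so that an
# isotropic emitter splits equally (1/2 each) between the channels and the
# emitted flux anisotropy of a cos^2-photoselected population is 0.4.
detection_weights <- function(grid, dipole_angle_abs_em = 0) {
  p2b <- (3 * cos(dipole_angle_abs_em)^2 - 1) / 2
  list(parallel      = 1.5 * (1 / 3 + p2b * (grid$mu_x^2 - 1 / 3)),
       perpendicular = 1.5 * (1 / 3 + p2b * (grid$mu_y^2 - 1 / 3)))
}

# reaction (switching + emission) part of one Strang step; constant rates
# within the step allow exact per-cell updates
react_populations <- function(field, illum, fluor, dt) {
  grid <- field$grid
  pop <- field$pop
  photons <- c(parallel = 0, perpendicular = 0, total = 0)
  if (illum$role == "switch_on_405") {
    k_on <- kernel_on_grid(grid, illum, fluor$k_on_peak)
    surv <- exp(-k_on * dt)
    pop$ON <- pop$ON + pop$OFF * (1 - surv)
    pop$OFF <- pop$OFF * surv
  } else {                               # probe_488: OFF-switch + emit
    k_off <- kernel_on_grid(grid, illum, fluor$k_off_peak)
    k_exc <- kernel_on_grid(grid, illum, fluor$k_exc_peak)
    b <- fluor$bleach_rate
    ktot <- k_off + b
    on0 <- pop$ON
    on1 <- on0 * exp(-ktot * dt)
    int_on <- on0 * .em1(ktot, dt)       # time integral of ON over the step
    loss <- on0 - on1
    br_off <- ifelse(ktot > 0, k_off / pmax(ktot, .Machine$double.xmin), 0)
    if (is.null(fluor$intermediate_rate)) {
      pop$OFF <- pop$OFF + loss * br_off
    } else {
      q <- fluor$intermediate_rate
      int0 <- pop$INTERMEDIATE
      denom <- ktot - q
      grow <- ifelse(abs(denom) > 1e-9 * q,
                     (exp(-q * dt) - exp(-ktot * dt)) / denom,
                     dt * exp(-q * dt))
      int1 <- int0 * exp(-q * dt) + on0 * k_off * grow
      pop$INTERMEDIATE <- int1
      pop$OFF <- pop$OFF + loss - (int1 - int0) - loss * (1 - br_off)
    }
    if (b > 0) pop$BLEACHED <- pop$BLEACHED + loss * (1 - br_off)
    pop$ON <- on1
    wdet <- detection_weights(grid, fluor$dipole_angle_abs_em)
    base <- fluor$brightness * grid$cellw * k_exc * int_on
    photons <- c(parallel = sum(base * wdet$parallel),
                 perpendicular = sum(base * wdet$perpendicular),
                 total = sum(base))
  }
  field$pop <- pop
  list(field = field, photons = photons)
}

#' Evolve the orientation-resolved populations over one time step
#'
#' Strang operator splitting: a half step of rotational diffusion, an exact
#' reaction step (photoswitching, optional ground-state intermediate and
#' bleaching, with the fluorescence emission integrated in closed form over
#' the step), then a second diffusion half step. 405-nm light drives only
#' OFF -> ON; 488-nm probe light drives ON -> OFF (optionally through the
#' intermediate) and generates the detected fluorescence, with every rate
#' weighted by the photoselection kernel of [excitation_rate_kernel()].
#'
#' @param field an [orientation_field()].
#' @param illum a [illumination()] object, or `NULL` for a dark interval
#'   (pure diffusion).
#' @param fluor a [fluorophore_model()].
#' @param rotor a [rotor_model()]; only `D_r` is used (static mixtures are
#'   handled by the scheme simulators).
#' @param dt step length, seconds. The spectral diffusion step is exact for
#'   any `dt`; accuracy of the splitting requires `max(rate) * dt` small
#'   (the scheme drivers sub-step to `max(rate) * dt <= 0.1`).
#' @return A list with elements `field` (the evolved field), `photons`
#'   (expected detected photons in the step, named `parallel`,
#'   `perpendicular`, `total`, before any detector gain; `total` is the
#'   orientation-independent emission integral used by unpolarized
#'   detection) and `flux` (`photons / dt`, photons/s).
#' @export
evolve_populations <- function(field, illum, fluor, rotor, dt) {
  stopifnot(inherits(field, "orientation_field"),
            inherits(fluor, "starss_fluorophore"),
            inherits(rotor, "starss_rotor"),
            is.numeric(dt), length(dt) == 1, dt > 0)
  if (!is.null(illum) && !is.null(fluor$intermediate_rate) &&
      !("INTERMEDIATE" %in% names(field$pop)))
    stop("field lacks an INTERMEDIATE state but the fluorophore enables one")
  if (is.null(illum)) {
    field <- propagate_rotation(field, rotor$D_r, dt)
    return(list(field = field,
                photons = c(parallel = 0, perpendicular = 0, total = 0),
                flux = c(parallel = 0, perpendicular = 0, total = 0)))
  }
  stopifnot(inherits(illum, "starss_illumination"))
  field <- propagate_rotation(field, rotor$D_r, dt / 2)
  r <- react_populations(field, illum, fluor, dt)
  field <- propagate_rotation(r$field, rotor$D_r, dt / 2)
  list(field = field, photons = r$photons, flux = r$photons / dt)
}

# segment-compiled reactor: precomputes every orientation kernel, decay
# factor and weighted emission integral for a fixed (illumination, dt), so
# the inner time loop reduces to a few elementwise products per step.
# Same math as react_populations, hoisted out of the loop.
make_reactor <- function(grid, illum, fluor, dt) {
  if (illum$role == "switch_on_405") {
    surv <- exp(-kernel_on_grid(grid, illum, fluor$k_on_peak) * dt)
    return(function(pop) {
      moved <- pop$OFF * (1 - surv)
      pop$ON <- pop$ON + moved
      pop$OFF <- pop$OFF - moved
      list(pop = pop, photons = c(parallel = 0, perpendicular = 0, total = 0))
    })
  }
  k_off <- kernel_on_grid(grid, illum, fluor$k_off_peak)
  k_exc <- kernel_on_grid(grid, illum, fluor$k_exc_peak)
  b <- fluor$bleach_rate
  ktot <- k_off + b
  surv <- exp(-ktot * dt)
  br_off <- ifelse(ktot > 0, k_off / pmax(ktot, .Machine$double.xmin), 0)
  wdet <- detection_weights(grid, fluor$dipole_angle_abs_em)
  base <- fluor$brightness * grid$cellw * k_exc * .em1(ktot, dt)
  A_par <- base * wdet$parallel
  A_perp <- base * wdet$perpendicular
  q <- fluor$intermediate_rate
  if (!is.null(q)) {
    dq <- exp(-q * dt)
    denom <- ktot - q
    grow <- ifelse(abs(denom) > 1e-9 * q,
                   (dq - surv) / denom, dt * dq) * k_off
  }
  to_bleach <- if (b > 0) (1 - surv) * (1 - br_off) else NULL
  function(pop) {
    on0 <- pop$ON
    photons <- c(parallel = sum(A_par * on0),
                 perpendicular = sum(A_perp * on0),
                 total = sum(base * on0))
    on1 <- on0 * surv
    loss <- on0 - on1
    if (is.null(q)) {
      pop$OFF <- pop$OFF + loss * br_off
    } else {
      int0 <- pop$INTERMEDIATE
      int1 <- int0 * dq + on0 * grow
      pop$INTERMEDIATE <- int1
      pop$OFF <- pop$OFF + loss * br_off - (int1 - int0)
    }
    if (!is.null(to_bleach)) pop$BLEACHED <- pop$BLEACHED + on0 * to_bleach
    pop$ON <- on1
    list(pop = pop, photons = photons)
  }
}

#' Orientation-averaged ON fraction after an ON-switching pulse
#'
#' For an initially fully OFF, isotropic population the pulse leaves each
#' orientation OFF with probability `exp(-k_on(Omega) * duration)`; the
#' returned value is the solid-angle average of the switched fraction.
#' Monotone in fluence, saturating at 1.
#'
#' @param pulse a 405-nm [illumination()].
#' @param fluor a [fluorophore_model()].
#' @return ON fraction in `[0, 1]`.
#' @examples
#' fl <- fluorophore_preset("rsEGFP2")
#' onswitch_fraction(illumination("switch_on_405", "linear", 0, 250e-9), fl)
#' @export
onswitch_fraction <- function(pulse, fluor) {
  stopifnot(inherits(pulse, "starss_illumination"),
            inherits(fluor, "starss_fluorophore"))
  if (pulse$role != "switch_on_405")
    stop("onswitch_fraction needs a switch_on_405 pulse")
  a <- fluor$k_on_peak * pulse$power_density * pulse$duration
  if (a == 0) return(0)
  # any fixed component of a uniformly random unit vector is uniform on [-1, 1]
  f <- if (pulse$polarization == "linear")
    function(u) exp(-a * u^2)
  else
    function(u) exp(-a * (1 - u^2) / 2)
  1 - integrate(f, 0, 1, rel.tol = 1e-10)$value
}

#' Calibrate 405-nm power density to a target ON fraction
#'
#' Inverts [onswitch_fraction()] by root-finding over power density, holding
#' the pulse duration fixed.
#'
#' @param target_fraction desired orientation-averaged ON fraction in (0, 1).
#' @param fluor a [fluorophore_model()].
#' @param duration pulse duration, seconds. Default 250 ns.
#' @param polarization,axis pulse polarization (see [illumination()]).
#' @return the calibrated 405-nm [illumination()].
#' @export
calibrate_on_power <- function(target_fraction, fluor, duration = 250e-9,
                               polarization = "linear", axis = c(1, 0, 0)) {
  stopifnot(target_fraction > 0, target_fraction < 1, fluor$k_on_peak > 0)
  fn <- function(lp) {
    pulse <- illumination("switch_on_405", polarization, 10^lp, duration,
                          axis = axis)
    onswitch_fraction(pulse, fluor) - target_fraction
  }
  lp <- uniroot(fn, c(-12, 18), tol = 1e-12)$root
  illumination("switch_on_405", polarization, 10^lp, duration, axis = axis)
}
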