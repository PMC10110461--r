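#' One segment of a pulse scheme
#'
#' An illumination (or dark) interval, optionally with time-binned photon
#' detection.
#'
#' @param illum a [illumination()] object, or `NULL` for a dark interval.
#' @param duration seconds; defaults to `illum$duration`.
#' @param detect logical; record time-binned photon counts?
#' @param bin_width detection bin width, seconds (>= 10 ns); must divide
#'   the duration to within one bin.
#' @param label segment label, e.g. `"probe"` or `"reset"`.
#' @param rate_dt sub-stepping accuracy target: the segment is advanced in
#'   sub-steps with `max(rate) * dt <= rate_dt`. Default 0.1; reset
#'   segments use a coarse value since only their depletion end point
#'   matters (the per-cell kinetics are exact at any step).
#' @return An object of class `scheme_segment`.
#' @export
scheme_segment <- function(illum = NULL, duration = NULL, detect = FALSE,
                           bin_width = NULL, label = "", rate_dt = 0.1) {
  if (is.null(duration)) {
    if (is.null(illum)) stop("a dark segment needs an explicit duration")
    duration <- illum$duration
  }
  stopifnot(is.numeric(duration), duration > 0)
  if (detect) {
    stopifnot(is.numeric(bin_width), bin_width >= 10e-9)
    n_bins <- max(1L, round(duration / bin_width))
    if (abs(n_bins * bin_width - duration) > bin_width * (1 + 1e-9))
      stop("bin_width must divide the segment duration to within one bin")
    duration <- n_bins * bin_width
  } else n_bins <- 0L
  structure(list(illum = illum, duration = duration, detect = detect,
                 bin_width = bin_width, n_bins = n_bins, label = label,
                 rate_dt = rate_dt),
            class = "scheme_segment")
}

#' Ordered illumination and detection program
#'
#' @param segments list of [scheme_segment()]s, executed in order.
#' @param cycles repetition count; expected counts scale linearly with
#'   cycles (the scheme is assumed to end fully reset, which is why a
#'   trailing reset segment is required for `cycles > 1`).
#' @param preset optional preset tag (`"method1"`, `"method2"`,
#'   `"method3"`, `"single_pulse_reference"`).
#' @return An object of class `pulse_scheme`.
#' @export
pulse_scheme <- function(segments, cycles = 1, preset = NULL) {
  stopifnot(length(segments) >= 1,
            all(vapply(segments, inherits, TRUE, "scheme_segment")),
            is.numeric(cycles), cycles >= 1)
  if (cycles > 1 &&
      segments[[length(segments)]]$label != "reset")
    stop("a scheme with cycles > 1 must end with a reset segment")
  structure(list(segments = segments, cycles = cycles, preset = preset),
            class = "pulse_scheme")
}

# largest kinetic rate active under an illumination, for sub-stepping
max_active_rate <- function(illum, fluor) {
  if (is.null(illum)) return(0)
  p <- illum$power_density
  if (illum$role == "switch_on_405") fluor$k_on_peak * p
  else max(fluor$k_off_peak * p + fluor$bleach_rate,
           fluor$intermediate_rate %||% 0)
}

# run one scheme for a single rigid-rotor component; returns expected
# photons per detection bin (per cycle, unit total population, before
# detector gain) plus the final field
run_scheme_component <- function(scheme, fluor, D_r, grid,
                                 init = "OFF") {
  field <- orientation_field(grid, init = init)
  t0 <- 0
  out <- list()
  diffuse <- function(f, dt) {
    if (D_r > 0) f$pop <- lapply(f$pop, function(p) {
      if (all(p == p[1])) p else diffuse_density(grid, p, D_r, dt)
    })
    f
  }
  for (seg in scheme$segments) {
    if (is.null(seg$illum)) {
      field <- diffuse(field, seg$duration)       # exact, one step
      t0 <- t0 + seg$duration
      next
    }
    # merged Strang composition over the whole segment:
    # D(dt/2) [R(dt) D(dt)]^(n-1) R(dt) D(dt/2)
    if (!seg$detect) {
      n_sub <- min(5000L, max(1L, ceiling(max_active_rate(seg$illum, fluor) *
                                            seg$duration / seg$rate_dt)))
      dt <- seg$duration / n_sub
      react <- make_reactor(grid, seg$illum, fluor, dt)
      field <- diffuse(field, dt / 2)
      for (i in seq_len(n_sub)) {
        field$pop <- react(field$pop)$pop
        field <- diffuse(field, if (i < n_sub) dt else dt / 2)
      }
      t0 <- t0 + seg$duration
      next
    }
    n_sub <- min(1000L, max(1L, ceiling(max_active_rate(seg$illum, fluor) *
                                          seg$bin_width / seg$rate_dt)))
    dt <- seg$bin_width / n_sub
    react <- make_reactor(grid, seg$illum, fluor, dt)
    ppar <- pperp <- ptot <- numeric(seg$n_bins)
    field <- diffuse(field, dt / 2)
    n_tot <- seg$n_bins * n_sub
    step <- 0L
    for (b in seq_len(seg$n_bins)) {
      acc <- c(0, 0, 0)
      for (i in seq_len(n_sub)) {
        step <- step + 1L
        rp <- react(field$pop)
        field$pop <- rp$pop
        acc <- acc + rp$photons
        field <- diffuse(field, if (step < n_tot) dt else dt / 2)
      }
      ppar[b] <- acc[1]; pperp[b] <- acc[2]; ptot[b] <- acc[3]
    }
    out[[length(out) + 1]] <- data.frame(
      time = t0 + (seq_len(seg$n_bins) - 0.5) * seg$bin_width,
      bin_width = seg$bin_width, photons_parallel = ppar,
      photons_perpendicular = pperp, photons_total = ptot,
      segment = if (nzchar(seg$label)) seg$label else "detect")
    t0 <- t0 + seg$duration
  }
  list(bins = if (length(out)) do.call(rbind, out) else NULL, field = field)
}

# expected per-bin signal for a (possibly static-mixture) rotor
run_scheme_expect <- function(scheme, fluor, rotor, grid, init = "OFF") {
  comps <- list()
  if (rotor$static_fraction < 1)
    comps[[length(comps) + 1]] <- list(w = 1 - rotor$static_fraction,
                                       D_r = rotor$D_r)
  if (rotor$static_fraction > 0)
    comps[[length(comps) + 1]] <- list(w = rotor$static_fraction, D_r = 0)
  bins <- NULL
  for (cc in comps) {
    r <- run_scheme_component(scheme, fluor, cc$D_r, grid, init = init)
    if (is.null(r$bins)) next
    if (is.null(bins)) {
      bins <- r$bins
      for (col in c("photons_parallel", "photons_perpendicular",
                    "photons_total"))
        bins[[col]] <- cc$w * bins[[col]]
    } else {
      for (col in c("photons_parallel", "photons_perpendicular",
                    "photons_total"))
        bins[[col]] <- bins[[col]] + cc$w * r$bins[[col]]
    }
  }
  bins
}

#' Time-binned polarization-resolved photon counts
#'
#' Container for the output of the scheme simulators (and for per-region
#' aggregates from image records): expected or Poisson-sampled counts in
#' the parallel and perpendicular channels per time bin.
#'
#' @param bin_centers bin centers, seconds, strictly increasing.
#' @param counts_parallel,counts_perpendicular nonnegative counts
#'   (expectations or sampled integers).
#' @param bin_width scalar or per-bin widths, seconds.
#' @param segment per-bin segment labels.
#' @param metadata free-form list (scheme, detector, cycles, seed, ...).
#' @return An object of class `decay_curve`.
#' @export
decay_curve <- function(bin_centers, counts_parallel, counts_perpendicular,
                        bin_width, segment = rep("detect", length(bin_centers)),
                        metadata = list()) {
  stopifnot(length(bin_centers) == length(counts_parallel),
            length(bin_centers) == length(counts_perpendicular),
            all(diff(bin_centers) > 0),
            all(counts_parallel >= 0), all(counts_perpendicular >= 0))
  structure(list(bin_centers = bin_centers,
                 counts_parallel = counts_parallel,
                 counts_perpendicular = counts_perpendicular,
                 bin_width = rep_len(bin_width, length(bin_centers)),
                 segment = segment, metadata = metadata),
            class = "decay_curve")
}

#' @export
print.decay_curve <- function(x, ...) {
  cat(sprintf(paste0("<decay_curve> %d bins (%s), %g--%g s, ",
                     "%.4g / %.4g photons (par/perp)%s\n"),
              length(x$bin_centers),
              paste(unique(x$segment), collapse = "+"),
              min(x$bin_centers), max(x$bin_centers),
              sum(x$counts_parallel), sum(x$counts_perpendicular),
              if (isTRUE(x$metadata$sampled)) ", Poisson-sampled" else ", expectation"))
  invisible(x)
}

#' @export
as.data.frame.decay_curve <- function(x, ...) {
  data.frame(time_s = x$bin_centers, counts_par = x$counts_parallel,
             counts_perp = x$counts_perpendicular, bin_width_s = x$bin_width,
             segment = x$segment)
}

# assemble a decay_curve from expected per-cycle signal bins: apply
# detector gains/backgrounds, cycles, optional photon-budget rescale and
# Poisson sampling
finalize_curve <- function(bins, detector, cycles, seed, sample,
                           target_photons = NULL, metadata = list()) {
  sig_par <- bins$photons_parallel * cycles
  sig_perp <- bins$photons_perpendicular * cycles / detector$g_factor
  if (!is.null(target_photons)) {
    tot <- sum(sig_par) + sum(sig_perp)
    if (tot <= 0) stop("no signal photons; cannot scale to target_photons")
    sc <- target_photons / tot
    sig_par <- sig_par * sc; sig_perp <- sig_perp * sc
    metadata$photon_scale <- sc
  }
  bg <- (detector$background_rate + detector$dark_rate) * bins$bin_width * cycles
  mu_par <- sig_par + bg
  mu_perp <- sig_perp + bg
  if (sample) {
    cpar <- with_stage_seed(seed, "poisson", {
      a <- rpois(length(mu_par), mu_par)
      b <- rpois(length(mu_perp), mu_perp)
      list(a, b)
    })
    mu_par <- cpar[[1]]; mu_perp <- cpar[[2]]
  }
  metadata$sampled <- sample
  metadata$cycles <- cycles
  metadata$seed <- seed
  metadata$detector <- unclass(detector)
  decay_curve(bins$time, mu_par, mu_perp, bins$bin_width,
              segment = bins$segment, metadata = metadata)
}

default_reset <- function(fluor, power = 2e4, duration = 5e-4,
                          bin_width = 1e-5, detect = TRUE) {
  scheme_segment(illumination("probe_488", "circular", power, duration),
                 detect = detect, bin_width = bin_width, label = "reset",
                 rate_dt = 5)
}

#' Simulate STARSS method 1 (ON-switching photoselection)
#'
#' A short linearly polarized 405-nm pulse photoselects a small, oriented
#' subset of molecules into the ON state; a long circularly polarized
#' 488-nm probe then reads their fluorescence in the two polarization
#' channels while slowly switching them OFF. The anisotropy of the binned
#' counts decays with the rotational correlation time of the rotor. A
#' trailing high-power reset segment (also recorded) returns the system to
#' all-OFF and exposes the cross-talk background.
#'
#' @param fluor a [fluorophore_model()].
#' @param rotor a [rotor_model()].
#' @param detector a [detector_pair()].
#' @param pulse_405 the photoselection pulse; default: 250-ns linear pulse
#'   along x calibrated with [calibrate_on_power()] to `on_fraction`.
#' @param probe_488 the probe; default 1 ms circular at 1 kW/cm^2.
#' @param on_fraction target ON fraction for the default pulse. Default
#'   0.10.
#' @param cycles number of scheme repetitions accumulated.
#' @param seed integer seed (enables Poisson sampling unless `sample` says
#'   otherwise); `NULL` for noiseless expectations.
#' @param sample draw Poisson counts? Defaults to `TRUE` when a seed is
#'   given.
#' @param bin_width probe detection bin width, seconds. Default 2 us.
#' @param grid a [sphere_grid()]; default 64 x 128.
#' @param reset append the reset segment? Default `TRUE`.
#' @param reset_power,reset_duration,reset_bin_width reset parameters.
#' @param target_photons optional total expected signal-photon budget; the
#'   signal expectation is rescaled to it before sampling.
#' @return A [decay_curve()] with segments `"probe"` and `"reset"`.
#' @examples
#' \donttest{
#' fl <- fluorophore_preset("rsEGFP2")
#' cur <- simulate_method1(fl, rotor_model(diameter = 100e-9),
#'                         grid = sphere_grid(32, 64))
#' }
#' @export
simulate_method1 <- function(fluor, rotor, detector = detector_pair(),
                             pulse_405 = NULL, probe_488 = NULL,
                             on_fraction = 0.10, cycles = 1, seed = NULL,
                             sample = !is.null(seed), bin_width = 2e-6,
                             grid = NULL, reset = TRUE, reset_power = 2e4,
                             reset_duration = 5e-4,
                             reset_bin_width = 1e-5,
                             target_photons = NULL) {
  grid <- grid %||% sphere_grid()
  pulse_405 <- pulse_405 %||% calibrate_on_power(on_fraction, fluor)
  if (pulse_405$role != "switch_on_405" || pulse_405$polarization != "linear")
    stop("method 1 photoselection uses a linear 405-nm pulse")
  probe_488 <- probe_488 %||% illumination("probe_488", "circular", 1e3, 1e-3)
  if (probe_488$role != "probe_488" || probe_488$polarization != "circular")
    stop("method 1 probing uses circular 488-nm light")
  if (-expm1(-fluor$k_off_peak * probe_488$power_density * bin_width) > 0.99)
    warning("probe so intense that >99% OFF-switch within one bin; decay undersampled")
  segs <- list(scheme_segment(pulse_405, label = "pulse405"),
               scheme_segment(probe_488, detect = TRUE,
                              bin_width = bin_width, label = "probe"))
  if (reset)
    segs <- c(segs, list(default_reset(fluor, reset_power, reset_duration,
                                       reset_bin_width)))
  scheme <- pulse_scheme(segs, cycles = cycles, preset = "method1")
  bins <- run_scheme_expect(scheme, fluor, rotor, grid)
  finalize_curve(bins, detector, cycles, seed, sample, target_photons,
                 metadata = list(method = "method1",
                                 fluorophore = fluor$name,
                                 rotor = unclass(rotor),
                                 on_fraction = on_fraction,
                                 pulse_405 = unclass(pulse_405),
                                 probe_488 = unclass(probe_488)))
}

#' Simulate STARSS method 2 (OFF-switching photoselection)
#'
#' All molecules start ON (circular 405-nm activation, saturated by
#' default); a linearly polarized 488-nm probe then simultaneously excites
#' fluorescence and OFF-switches the aligned molecules. When OFF-switching
#' outcompetes rotation the parallel channel is depleted faster and the
#' anisotropy decays; when rotation is faster the orientations reshuffle
#' and the anisotropy is stationary.
#'
#' @inheritParams simulate_method1
#' @param activation_405 circular activation pulse; `NULL` (default) uses
#'   the saturated limit and initializes the field fully ON. Give a pulse
#'   to model partial activation.
#' @param on_fraction activation ON fraction; 1 (default) means the
#'   saturated all-ON limit, values < 1 calibrate a circular pulse.
#' @param probe_488 linear probe; default 1 ms along x at 1 kW/cm^2.
#' @return A [decay_curve()].
#' @export
simulate_method2 <- function(fluor, rotor, detector = detector_pair(),
                             activation_405 = NULL, probe_488 = NULL,
                             on_fraction = 1, cycles = 1, seed = NULL,
                             sample = !is.null(seed), bin_width = 2e-6,
                             grid = NULL, reset = TRUE, reset_power = 2e4,
                             reset_duration = 5e-4, reset_bin_width = 1e-5,
                             target_photons = NULL) {
  grid <- grid %||% sphere_grid()
  probe_488 <- probe_488 %||% illumination("probe_488", "linear", 1e3, 1e-3,
                                           axis = c(1, 0, 0))
  if (probe_488$role != "probe_488" || probe_488$polarization != "linear")
    stop("method 2 probing uses linear 488-nm light")
  init <- "OFF"
  segs <- list()
  if (is.null(activation_405) && on_fraction >= 1) {
    init <- "ON"                      # saturated circular activation limit
  } else {
    activation_405 <- activation_405 %||%
      calibrate_on_power(on_fraction, fluor, duration = 250e-9,
                         polarization = "circular")
    if (activation_405$role != "switch_on_405" ||
        activation_405$polarization != "circular")
      stop("method 2 activation uses circular 405-nm light")
    segs <- list(scheme_segment(activation_405, label = "pulse405"))
  }
  segs <- c(segs, list(scheme_segment(probe_488, detect = TRUE,
                                      bin_width = bin_width, label = "probe")))
  if (reset)
    segs <- c(segs, list(default_reset(fluor, reset_power, reset_duration,
                                       reset_bin_width)))
  scheme <- pulse_scheme(segs, cycles = cycles, preset = "method2")
  bins <- run_scheme_expect(scheme, fluor, rotor, grid, init = init)
  finalize_curve(bins, detector, cycles, seed, sample, target_photons,
                 metadata = list(method = "method2",
                                 fluorophore = fluor$name,
                                 rotor = unclass(rotor),
                                 on_fraction = on_fraction,
                                 probe_488 = unclass(probe_488)))
}

#' Delay-series counts from a pump-pump-probe scheme
#'
#' Container for method-3 output: total probed counts versus the delay
#' between the two ON-switching pulses, normalized by a matched
#' single-pulse reference acquisition.
#'
#' @param delays delays, seconds.
#' @param total_counts total probed counts per delay.
#' @param reference_counts single-pulse reference total.
#' @param metadata free-form list.
#' @return An object of class `modulation_curve` with `normalized =
#'   total_counts / reference_counts`.
#' @export
modulation_curve <- function(delays, total_counts, reference_counts,
                             metadata = list()) {
  stopifnot(length(delays) == length(total_counts),
            all(total_counts >= 0), length(reference_counts) == 1,
            reference_counts > 0)
  structure(list(delays = delays, total_counts = total_counts,
                 reference_counts = reference_counts,
                 normalized = total_counts / reference_counts,
                 metadata = metadata),
            class = "modulation_curve")
}

#' @export
print.modulation_curve <- function(x, ...) {
  cat(sprintf("<modulation_curve> %d delays, %g--%g s, normalized %0.4g--%0.4g\n",
              length(x$delays), min(x$delays), max(x$delays),
              min(x$normalized), max(x$normalized)))
  invisible(x)
}

#' @export
as.data.frame.modulation_curve <- function(x, ...) {
  data.frame(delay_s = x$delays, total_counts = x$total_counts,
             reference_counts = x$reference_counts,
             norm_counts = x$normalized)
}

#' Simulate STARSS method 3 (delayed pulse-pair photoselection)
#'
#' Two identical linearly polarized ~50-ns 405-nm pulses, separated by a
#' variable delay, drive molecules into the ON state; circular 488-nm
#' light then reads out the total fluorescence. By default the detector
#' is unpolarized (the scheme needs no polarization-sensitive detection),
#' so the observable is the orientation-independent total emission;
#' `polarization_resolved = TRUE` records the two analyzer channels
#' instead and sums them.
#' The first pulse preferentially switches aligned molecules; if the
#' remaining OFF pool rotates during the delay, the second pulse finds
#' fresh aligned molecules and the total ON population -- and hence the
#' probed signal -- increases with delay. Counts are normalized by a
#' matched single-pulse reference scheme.
#'
#' @inheritParams simulate_method1
#' @param delays vector of pulse-pair delays, seconds; each must be at
#'   least the pulse duration.
#' @param pulse_405 the first pulse; default 50-ns linear along x,
#'   calibrated to `on_fraction_first`.
#' @param pulse_405_second the second pulse; defaults to the first.
#' @param on_fraction_first ON fraction of the first pulse for the default
#'   calibration. Default 0.5.
#' @param probe_488 readout; default 1 ms circular at 2 kW/cm^2 (nearly
#'   complete depletion, so totals report the ON mass).
#' @param probe_bin_width internal binning of the probe, seconds.
#' @param polarization_resolved keep per-channel totals as well?
#' @return A [modulation_curve()].
#' @export
simulate_method3 <- function(fluor, rotor, detector = detector_pair(),
                             delays, pulse_405 = NULL,
                             pulse_405_second = NULL,
                             on_fraction_first = 0.5, probe_488 = NULL,
                             cycles = 1, seed = NULL,
                             sample = !is.null(seed), grid = NULL,
                             probe_bin_width = 2e-5,
                             polarization_resolved = FALSE) {
  grid <- grid %||% sphere_grid()
  pulse_405 <- pulse_405 %||% calibrate_on_power(on_fraction_first, fluor,
                                                 duration = 50e-9)
  pulse_405_second <- pulse_405_second %||% pulse_405
  for (p in list(pulse_405, pulse_405_second))
    if (p$role != "switch_on_405" || p$polarization != "linear" ||
        any(p$axis != pulse_405$axis))
      stop("method 3 uses linear 405-nm pulses along a shared axis")
  stopifnot(length(delays) >= 1, all(is.finite(delays)))
  if (any(delays < pulse_405$duration))
    stop("delays shorter than the pulse duration are rejected")
  probe_488 <- probe_488 %||% illumination("probe_488", "circular", 2e3, 1e-3)
  probe_seg <- scheme_segment(probe_488, detect = TRUE,
                              bin_width = probe_bin_width, label = "probe")
  run_total <- function(segs) {
    scheme <- pulse_scheme(segs, cycles = 1, preset = "method3")
    bins <- run_scheme_expect(scheme, fluor, rotor, grid)
    c(par = sum(bins$photons_parallel) * cycles,
      perp = sum(bins$photons_perpendicular) * cycles / detector$g_factor,
      tot = sum(bins$photons_total) * cycles)
  }
  ref <- run_total(list(scheme_segment(pulse_405, label = "pulse1"),
                        probe_seg))
  tot <- t(vapply(delays, function(d) {
    run_total(list(scheme_segment(pulse_405, label = "pulse1"),
                   scheme_segment(illum = NULL, duration = d, label = "delay"),
                   scheme_segment(pulse_405_second, label = "pulse2"),
                   probe_seg))
  }, c(par = 0, perp = 0, tot = 0)))
  bgc <- (detector$background_rate + detector$dark_rate) *
    probe_seg$duration * cycles
  if (polarization_resolved) {
    tot_sum <- tot[, "par"] + tot[, "perp"] + 2 * bgc
    ref_sum <- ref[["par"]] + ref[["perp"]] + 2 * bgc
  } else {
    tot_sum <- tot[, "tot"] + bgc
    ref_sum <- ref[["tot"]] + bgc
  }
  if (sample) {
    s <- with_stage_seed(seed, "poisson", {
      list(rpois(length(tot_sum), tot_sum), rpois(1, ref_sum))
    })
    tot_sum <- s[[1]]; ref_sum <- max(1, s[[2]])
  }
  md <- list(method = "method3", fluorophore = fluor$name,
             rotor = unclass(rotor), cycles = cycles, seed = seed,
             sampled = sample, detector = unclass(detector),
             pulse_405 = unclass(pulse_405),
             probe_488 = unclass(probe_488),
             on_fraction_first = onswitch_fraction(pulse_405, fluor))
  if (polarization_resolved) {
    md$total_parallel <- tot[, "par"] + bgc
    md$total_perpendicular <- tot[, "perp"] + bgc
  }
  modulation_curve(delays, tot_sum, ref_sum, metadata = md)
}

#' Estimate the cross-talk background from the reset window
#'
#' The fluorescence level at the end of the OFF-switching reset segment is
#' the background due to cross-talk (plus dark counts); this takes the
#' mean count rate per channel over the trailing half of the reset bins.
#'
#' @param curve a [decay_curve()] whose `segment` labels include
#'   `"reset"` with at least 10 detected bins.
#' @param trailing_fraction fraction of the reset window used (from the
#'   end). Default 0.5.
#' @return An object of class `starss_background`: per-channel rates
#'   (counts/s) plus the per-bin expectation at the probe bin width.
#' @export
estimate_background <- function(curve, trailing_fraction = 0.5) {
  stopifnot(inherits(curve, "decay_curve"))
  idx <- which(curve$segment == "reset")
  if (length(idx) < 10)
    stop("no reset window with >= 10 bins; supply the background explicitly")
  keep <- tail(idx, max(1L, ceiling(length(idx) * trailing_fraction)))
  rate <- c(parallel = mean(curve$counts_parallel[keep] / curve$bin_width[keep]),
            perpendicular = mean(curve$counts_perpendicular[keep] /
                                   curve$bin_width[keep]))
  probe_bw <- curve$bin_width[curve$segment != "reset"][1] %||%
    curve$bin_width[1]
  structure(list(rate = rate, per_bin = rate * probe_bw,
                 n_bins = length(keep), bin_width = probe_bw),
            class = "starss_background")
}

#' @export
print.starss_background <- function(x, ...) {
  cat(sprintf("<starss_background> %.4g / %.4g counts/s (par/perp), %d reset bins\n",
              x$rate[1], x$rate[2], x$n_bins))
  invisible(x)
}

#' Simulate an isotropic steady reference (G-factor calibration record)
#'
#' An isotropic, fully ON population probed with circular 488-nm light:
#' both channels see the same flux, so the recorded channel ratio
#' estimates the detector gain ratio (see [calibrate_g()]). A fast rotor
#' keeps the sample isotropic against the probe's own photoselection.
#'
#' @inheritParams simulate_method1
#' @param probe_488 circular probe; default 0.3 kW/cm^2 for 1 ms.
#' @param rotor fast rotor emulating a free dye bar; default 100 ns.
#' @return A [decay_curve()].
#' @export
simulate_calibration_record <- function(fluor, detector = detector_pair(),
                                        probe_488 = NULL,
                                        rotor = rotor_model(tau = 1e-7),
                                        cycles = 1, seed = NULL,
                                        sample = !is.null(seed),
                                        bin_width = 5e-6, grid = NULL,
                                        target_photons = NULL) {
  grid <- grid %||% sphere_grid()
  probe_488 <- probe_488 %||% illumination("probe_488", "circular", 300, 1e-3)
  if (probe_488$polarization != "circular")
    stop("the calibration record uses circular excitation")
  scheme <- pulse_scheme(list(scheme_segment(probe_488, detect = TRUE,
                                             bin_width = bin_width,
                                             label = "probe")))
  bins <- run_scheme_expect(scheme, fluor, rotor, grid, init = "ON")
  finalize_curve(bins, detector, cycles, seed, sample, target_photons,
                 metadata = list(method = "calibration",
                                 fluorophore = fluor$name))
}
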