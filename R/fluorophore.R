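#' Reversibly switchable fluorophore model
#'
#' Rate constants and dipole geometry of a reversibly switchable fluorescent
#' protein (rsFP). Peak rates are per unit power density for a dipole
#' parallel to the polarization; the actual orientation-dependent rate is
#' obtained through [excitation_rate_kernel()].
#'
#' @param k_on_peak ON-switching rate per unit 405-nm power density for a
#'   dipole parallel to the field, 1/s per W/cm^2.
#' @param k_off_peak OFF-switching rate per unit 488-nm power density,
#'   1/s per W/cm^2.
#' @param k_exc_peak fluorescence excitation rate per unit 488-nm power
#'   density, 1/s per W/cm^2.
#' @param brightness expected detected photons per excitation event
#'   (dimensionless; folds in quantum yield and collection efficiency).
#' @param dipole_angle_abs_em angle between absorption and emission
#'   transition dipoles, radians in `[0, pi/2]`. Default 0 (collinear).
#' @param intermediate_rate optional return rate (1/s) of a dark
#'   ground-state intermediate between ON and OFF. When set, OFF-switching
#'   proceeds ON -> INTERMEDIATE -> OFF and becomes bi-exponential, with the
#'   slow component set by this rate. `NULL` (default) disables the state.
#' @param bleach_rate irreversible loss rate (1/s) applied to ON molecules
#'   while probe light is on. Default 0.
#' @param name optional label.
#' @return An object of class `starss_fluorophore`.
#' @examples
#' fluorophore_preset("rsEGFP2")
#' fluorophore_model(k_on_peak = 2e3, k_off_peak = 12, k_exc_peak = 2e4,
#'                   brightness = 0.05)
#' @export
fluorophore_model <- function(k_on_peak, k_off_peak, k_exc_peak, brightness,
                              dipole_angle_abs_em = 0,
                              intermediate_rate = NULL, bleach_rate = 0,
                              name = "custom") {
  rates <- c(k_on_peak, k_off_peak, k_exc_peak, brightness, bleach_rate)
  stopifnot(is.numeric(rates), all(is.finite(rates)), all(rates >= 0),
            is.numeric(dipole_angle_abs_em),
            dipole_angle_abs_em >= 0, dipole_angle_abs_em <= pi / 2 + 1e-12)
  if (!is.null(intermediate_rate))
    stopifnot(is.numeric(intermediate_rate), intermediate_rate > 0)
  structure(list(k_on_peak = k_on_peak, k_off_peak = k_off_peak,
                 k_exc_peak = k_exc_peak, brightness = brightness,
                 dipole_angle_abs_em = dipole_angle_abs_em,
                 intermediate_rate = intermediate_rate,
                 bleach_rate = bleach_rate, name = name),
            class = "starss_fluorophore")
}

#' Shipped fluorophore presets
#'
#' Reads one of the JSON presets under `extdata/fluorophores`. The shipped
#' rate constants are order-of-magnitude defaults for fast-switching rsFPs
#' (see each file's `provenance` field); they set realistic time scales for
#' simulation but are not fitted photophysical measurements.
#'
#' @param name `"rsEGFP2"` or `"DronpaM159T"`.
#' @param use_intermediate enable the dark ground-state intermediate stored
#'   in the preset (bi-exponential OFF-switching at high probe power).
#' @return A [fluorophore_model()] object.
#' @export
fluorophore_preset <- function(name = c("rsEGFP2", "DronpaM159T"),
                               use_intermediate = FALSE) {
  name <- match.arg(name)
  path <- system.file("extdata", "fluorophores", paste0(name, ".json"),
                      package = "starss", mustWork = TRUE)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  fluorophore_model(
    k_on_peak = p$k_on_peak, k_off_peak = p$k_off_peak,
    k_exc_peak = p$k_exc_peak, brightness = p$brightness,
    dipole_angle_abs_em = p$dipole_angle_abs_em %||% 0,
    intermediate_rate = if (use_intermediate) p$intermediate_rate else NULL,
    bleach_rate = p$bleach_rate %||% 0, name = p$name)
}

#' @export
print.starss_fluorophore <- function(x, ...) {
  cat(sprintf(paste0("<starss_fluorophore> %s\n",
                     "  k_on_peak %g, k_off_peak %g, k_exc_peak %g ",
                     "(1/s per W/cm^2)\n  brightness %g, dipole angle %g rad%s%s\n"),
              x$name, x$k_on_peak, x$k_off_peak, x$k_exc_peak, x$brightness,
              x$dipole_angle_abs_em,
              if (!is.null(x$intermediate_rate))
                sprintf(", intermediate rate %g 1/s", x$intermediate_rate) else "",
              if (x$bleach_rate > 0)
                sprintf(", bleach rate %g 1/s", x$bleach_rate) else ""))
  invisible(x)
}
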