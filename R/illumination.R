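#' Illumination pulse
#'
#' One polarized illumination episode. The optical axis is z; linear
#' polarization axes lie in the sample (x, y) plane, circular polarization
#' rotates in the plane perpendicular to the optical axis.
#'
#' @param role `"switch_on_405"` (drives OFF -> ON) or `"probe_488"`
#'   (excites fluorescence and drives ON -> OFF).
#' @param polarization `"linear"` or `"circular"`.
#' @param power_density W/cm^2.
#' @param duration seconds.
#' @param axis unit polarization vector for linear light; must lie in the
#'   sample plane. Default x.
#' @return An object of class `starss_illumination`.
#' @examples
#' illumination("switch_on_405", "linear", 5e3, 250e-9)
#' illumination("probe_488", "circular", 1e3, 1e-3)
#' @export
illumination <- function(role = c("switch_on_405", "probe_488"),
                         polarization = c("linear", "circular"),
                         power_density, duration, axis = c(1, 0, 0)) {
  role <- match.arg(role)
  polarization <- match.arg(polarization)
  stopifnot(is.numeric(power_density), length(power_density) == 1,
            is.finite(power_density), power_density >= 0,
            is.numeric(duration), length(duration) == 1,
            is.finite(duration), duration > 0)
  if (polarization == "linear") {
    if (length(axis) != 3 || !is.numeric(axis) ||
        abs(sqrt(sum(axis^2)) - 1) > 1e-8)
      stop("linear polarization axis must be a unit 3-vector")
    if (abs(axis[3]) > 1e-8)
      stop("linear polarization axis must be perpendicular to the optical axis (z)")
  } else {
    axis <- NULL
  }
  structure(list(role = role, polarization = polarization,
                 power_density = power_density, duration = duration,
                 axis = axis),
            class = "starss_illumination")
}

#' @export
print.starss_illumination <- function(x, ...) {
  cat(sprintf("<starss_illumination> %s, %s%s, %g W/cm^2, %g s\n",
              x$role, x$polarization,
              if (!is.null(x$axis))
                sprintf(" along (%g, %g, %g)", x$axis[1], x$axis[2], x$axis[3])
              else "",
              x$power_density, x$duration))
  invisible(x)
}

#' One-photon photoselection rate for a given dipole orientation
#'
#' The orientation dependence of every light-driven transition: for linear
#' polarization along unit vector e the rate is
#' `peak_rate * power_density * (mu . e)^2`; for circular polarization in
#' the plane perpendicular to the optical axis z it is
#' `peak_rate * power_density * (1 - mu_z^2) / 2`.
#'
#' @param dipole unit 3-vector, or an n x 3 matrix of unit rows.
#' @param illum a [illumination()] object.
#' @param peak_rate rate per unit power density for a parallel dipole,
#'   1/s per W/cm^2.
#' @return rate(s) in 1/s, same length as the number of dipoles.
#' @examples
#' il <- illumination("switch_on_405", "linear", 1, 1e-6, axis = c(1, 0, 0))
#' excitation_rate_kernel(c(1, 0, 0), il, 100)  # parallel: full rate
#' excitation_rate_kernel(c(0, 0, 1), il, 100)  # orthogonal: zero
#' @export
excitation_rate_kernel <- function(dipole, illum, peak_rate) {
  stopifnot(inherits(illum, "starss_illumination"),
            is.numeric(peak_rate), peak_rate >= 0)
  if (is.null(dim(dipole))) dipole <- matrix(dipole, nrow = 1)
  if (ncol(dipole) != 3) stop("dipole must have 3 components")
  nrm <- sqrt(rowSums(dipole^2))
  if (any(abs(nrm - 1) > 1e-8)) stop("dipole must be a unit vector")
  k <- peak_rate * illum$power_density
  if (illum$polarization == "linear") {
    proj <- drop(dipole %*% illum$axis)
    k * proj^2
  } else {
    k * (1 - dipole[, 3]^2) / 2
  }
}

# orientation-kernel field (n_theta x n_phi matrix) on a sphere grid,
# in 1/s; shape only when rate_power = 1
kernel_on_grid <- function(grid, illum, peak_rate) {
  k <- peak_rate * illum$power_density
  if (illum$polarization == "linear") {
    a <- illum$axis
    k * (a[1] * grid$mu_x + a[2] * grid$mu_y)^2
  } else {
    k * (1 - grid$mu_z^2) / 2
  }
}
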