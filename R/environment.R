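#' Solvent environment for rotational diffusion
#'
#' Bundles the absolute temperature and dynamic viscosity entering the
#' Stokes--Einstein--Debye relation. The Boltzmann constant is fixed at its
#' CODATA value internally.
#'
#' @param temperature absolute temperature in kelvin. Default 293 K.
#' @param viscosity dynamic viscosity in Pa s (1 cP = 1e-3 Pa s). Default
#'   1 cP, i.e. water at ~20 degrees C.
#' @return An object of class `starss_env`.
#' @examples
#' environment_params()                      # 293 K, 1 cP
#' environment_params(310, 1.5e-3)           # cytosol-like
#' @export
environment_params <- function(temperature = 293, viscosity = 1e-3) {
  stopifnot(is.numeric(temperature), length(temperature) == 1,
            is.finite(temperature), temperature > 0,
            is.numeric(viscosity), length(viscosity) == 1,
            is.finite(viscosity), viscosity > 0)
  structure(list(temperature = temperature, viscosity = viscosity,
                 boltzmann_constant = .kB),
            class = "starss_env")
}

#' @export
print.starss_env <- function(x, ...) {
  cat(sprintf("<starss_env> T = %g K, eta = %g Pa s (%g cP)\n",
              x$temperature, x$viscosity, x$viscosity / 1e-3))
  invisible(x)
}

#' Rotational correlation time of a sphere from its hydrodynamic diameter
#'
#' Stokes--Einstein--Debye: `tau_rot = eta * V_h / (k_B * T)` with hydrated
#' volume `V_h = (pi/6) d^3`, equivalently `tau_rot = 1/(6 D_r)` with
#' `D_r = k_B T / (8 pi eta (d/2)^3)`.
#'
#' @param diameter hydrodynamic diameter in metres.
#' @param env a [environment_params()] object.
#' @return rotational correlation time in seconds.
#' @examples
#' tau_from_diameter(5e-9)     # ~16.2 ns, a GFP-sized protein
#' tau_from_diameter(100e-9)   # ~130 us, a large particle
#' @seealso [diameter_from_tau()] for the inverse.
#' @export
tau_from_diameter <- function(diameter, env = environment_params()) {
  stopifnot(inherits(env, "starss_env"), is.numeric(diameter),
            all(is.finite(diameter)))
  if (any(diameter <= 0)) stop("diameter must be positive")
  pi * env$viscosity * diameter^3 / (6 * env$boltzmann_constant * env$temperature)
}

#' Hydrodynamic diameter from a rotational correlation time
#'
#' Exact inverse of [tau_from_diameter()]:
#' `d = (6 k_B T tau / (pi eta))^(1/3)`.
#'
#' @param tau rotational correlation time in seconds.
#' @inheritParams tau_from_diameter
#' @return hydrodynamic diameter in metres.
#' @examples
#' diameter_from_tau(22.2e-6) * 1e9   # ~55 nm
#' diameter_from_tau(8.1e-6) * 1e9    # ~40 nm
#' @export
diameter_from_tau <- function(tau, env = environment_params()) {
  stopifnot(inherits(env, "starss_env"), is.numeric(tau), all(is.finite(tau)))
  if (any(tau <= 0)) stop("tau must be positive")
  (6 * env$boltzmann_constant * env$temperature * tau / (pi * env$viscosity))^(1/3)
}

#' Rigid-rotor model
#'
#' A spherical rotor described by its rotational diffusion coefficient, plus
#' an optional static (immobile) sub-population. Exactly one of `D_r`, `tau`
#' or `diameter` must be given; `diameter` requires `env`.
#'
#' @param D_r rotational diffusion coefficient in 1/s.
#' @param tau rotational correlation time in seconds (`tau = 1/(6 D_r)`).
#' @param diameter hydrodynamic diameter in metres.
#' @param static_fraction fraction of molecules with `D_r = 0`, in `[0, 1]`;
#'   models immobile background such as surface-bound or very large objects.
#' @param env a [environment_params()] object, used only with `diameter`.
#' @return An object of class `starss_rotor` with elements `D_r`, `tau`
#'   (`Inf` when `D_r = 0`) and `static_fraction`.
#' @examples
#' rotor_model(tau = 30e-6)
#' rotor_model(diameter = 100e-9)
#' rotor_model(D_r = 0)            # fully static reference
#' @export
rotor_model <- function(D_r = NULL, tau = NULL, diameter = NULL,
                        static_fraction = 0, env = environment_params()) {
  given <- !c(is.null(D_r), is.null(tau), is.null(diameter))
  if (sum(given) != 1)
    stop("give exactly one of D_r, tau or diameter")
  if (!is.null(diameter)) tau <- tau_from_diameter(diameter, env)
  if (!is.null(tau)) {
    stopifnot(is.numeric(tau), length(tau) == 1, tau > 0)
    D_r <- 1 / (6 * tau)
  }
  stopifnot(is.numeric(D_r), length(D_r) == 1, is.finite(D_r), D_r >= 0,
            is.numeric(static_fraction), length(static_fraction) == 1,
            static_fraction >= 0, static_fraction <= 1)
  structure(list(D_r = D_r, tau = if (D_r > 0) 1 / (6 * D_r) else Inf,
                 static_fraction = static_fraction),
            class = "starss_rotor")
}

#' @export
print.starss_rotor <- function(x, ...) {
  cat(sprintf("<starss_rotor> D_r = %g 1/s (tau = %g s), static fraction %g\n",
              x$D_r, x$tau, x$static_fraction))
  invisible(x)
}

#' Contour length of a peptide linker in stretched conformation
#'
#' @param n_residues number of amino-acid residues.
#' @param rise_per_residue contour rise per residue in metres; default
#'   0.35 nm, the standard fully extended backbone value.
#' @return length in metres.
#' @examples
#' linker_contour_length(30) * 1e9   # 10.5 nm
#' @export
linker_contour_length <- function(n_residues, rise_per_residue = 0.35e-9) {
  stopifnot(is.numeric(n_residues), all(n_residues >= 0))
  n_residues * rise_per_residue
}
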