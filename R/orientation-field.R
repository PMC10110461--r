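#' Discretized unit sphere of dipole orientations
#'
#' Gauss--Legendre nodes in `cos(theta)` (theta measured from the optical
#' axis z) crossed with a uniform azimuthal grid. The grid carries the
#' quadrature weights, the Cartesian dipole components at every cell and the
#' precomputed normalized associated-Legendre tables used by the spectral
#' rotational-diffusion propagator. Grids are cached per resolution.
#'
#' @param n_theta number of polar nodes. Default 64.
#' @param n_phi number of azimuthal nodes, even. Default 128.
#' @param l_max spectral band limit of the diffusion propagator; default
#'   `min(n_theta - 1, 40)`. The photoswitching populations are smooth, so
#'   modes above l ~ 40 carry no physical content even under strongly
#'   saturated photoselection; raise it for pathological inputs.
#' @return An object of class `sphere_grid`.
#' @examples
#' g <- sphere_grid(32, 64)
#' sum(g$cellw)      # total solid angle, 4 pi
#' @export
sphere_grid <- function(n_theta = 64, n_phi = 128,
                        l_max = min(n_theta - 1, 40)) {
  stopifnot(n_theta >= 8, n_phi >= 8, n_phi %% 2 == 0,
            l_max >= 4, l_max <= n_theta - 1)
  key <- sprintf("grid_%d_%d_%d", n_theta, n_phi, l_max)
  if (!is.null(.starss_cache[[key]])) return(.starss_cache[[key]])
  gl <- pracma::gaussLegendre(n_theta, -1, 1)
  x <- gl$x; w <- gl$w
  phi <- 2 * pi * (0:(n_phi - 1)) / n_phi
  st <- sqrt(pmax(0, 1 - x^2))
  m_max <- min(l_max, n_phi / 2 - 1)
  grid <- structure(list(
    n_theta = n_theta, n_phi = n_phi, x = x, w = w, phi = phi,
    dphi = 2 * pi / n_phi,
    cellw = outer(w, rep(2 * pi / n_phi, n_phi)),
    mu_x = outer(st, cos(phi)),
    mu_y = outer(st, sin(phi)),
    mu_z = outer(x, rep(1, n_phi)),
    l_max = l_max, m_max = m_max,
    P = normalized_alf(x, l_max),
    l_seq = lapply(0:m_max, function(m) m:l_max)
  ), class = "sphere_grid")
  .starss_cache[[key]] <- grid
  grid
}

#' @export
print.sphere_grid <- function(x, ...) {
  cat(sprintf("<sphere_grid> %d x %d (theta x phi), l_max = %d\n",
              x$n_theta, x$n_phi, x$l_max))
  invisible(x)
}

# orthonormal (full-sphere, including azimuthal factor) associated Legendre
# functions: P[[m+1]] is a length(x) x (l_max - m + 1) matrix of
# \tilde P_l^m(x), l = m..l_max, with int \tilde P^2 dx = 1/(2 pi) so that
# \tilde P_l^m(x) e^{i m phi} are orthonormal over the sphere.
# Standard stable three-term recursion; no installed package provides the
# normalized transform, hence authored here.
normalized_alf <- function(x, l_max) {
  n <- length(x)
  P <- vector("list", l_max + 1)
  pmm <- rep(sqrt(1 / (4 * pi)), n)
  sx <- sqrt(pmax(0, 1 - x^2))
  for (m in 0:l_max) {
    cols <- matrix(0, n, l_max - m + 1)
    cols[, 1] <- pmm
    if (l_max > m) cols[, 2] <- x * sqrt(2 * m + 3) * pmm
    if (l_max > m + 1) for (l in (m + 2):l_max) {
      a <- sqrt((4 * l^2 - 1) / (l^2 - m^2))
      b <- sqrt(((l - 1)^2 - m^2) / (4 * (l - 1)^2 - 1))
      cols[, l - m + 1] <- a * (x * cols[, l - m] - b * cols[, l - m - 1])
    }
    P[[m + 1]] <- cols
    if (m < l_max) pmm <- -sqrt((2 * m + 3) / (2 * m + 2)) * sx * pmm
  }
  P
}

#' Integrate a function of orientation over the sphere
#'
#' @param grid a [sphere_grid()].
#' @param f an `n_theta x n_phi` matrix of values at the grid cells.
#' @return the integral over solid angle.
#' @export
sphere_integral <- function(grid, f) sum(grid$cellw * f)

#' Per-state molecular populations over orientation
#'
#' The forward model's state: a nonnegative density over the orientation
#' sphere for each molecular state (ON, OFF, and optionally a dark
#' ground-state INTERMEDIATE and an irreversibly BLEACHED sink). The total
#' mass (integral over states and orientations) is 1 for a fresh field and
#' is conserved by switching and rotation; only bleaching moves mass into
#' BLEACHED, where it still counts towards the total.
#'
#' @param grid a [sphere_grid()].
#' @param init state holding all mass initially (isotropic); default
#'   `"OFF"`.
#' @param states character vector of states to carry.
#' @return An object of class `orientation_field`.
#' @examples
#' f <- orientation_field(sphere_grid(32, 64))
#' field_mass(f)        # 1
#' @export
orientation_field <- function(grid, init = "OFF",
                              states = c("ON", "OFF", "INTERMEDIATE", "BLEACHED")) {
  stopifnot(inherits(grid, "sphere_grid"), init %in% states)
  pop <- lapply(states, function(s)
    matrix(if (s == init) 1 / (4 * pi) else 0, grid$n_theta, grid$n_phi))
  names(pop) <- states
  structure(list(grid = grid, pop = pop), class = "orientation_field")
}

#' Total population mass of a field
#'
#' @param field an [orientation_field()].
#' @param state optional single state name; default sums all states.
#' @return scalar mass.
#' @export
field_mass <- function(field, state = NULL) {
  stopifnot(inherits(field, "orientation_field"))
  if (!is.null(state)) return(sphere_integral(field$grid, field$pop[[state]]))
  sum(vapply(field$pop, function(p) sphere_integral(field$grid, p), 0))
}

#' @export
print.orientation_field <- function(x, ...) {
  m <- vapply(x$pop, function(p) sphere_integral(x$grid, p), 0)
  cat(sprintf("<orientation_field> %d x %d grid; mass: %s\n",
              x$grid$n_theta, x$grid$n_phi,
              paste(sprintf("%s %.4g", names(m), m), collapse = ", ")))
  invisible(x)
}

# validity check used by the propagator and scheme drivers
check_field <- function(field, tol = 1e-9) {
  neg <- min(vapply(field$pop, min, 0))
  if (neg < -tol)
    stop(sprintf("orientation field has negative density (%g)", neg))
  invisible(field)
}
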