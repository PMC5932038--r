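#' One-dimensional potential
#'
#' Bundles a potential energy function `U(z)` (kJ/mol over z in nm) with its
#' force `F(z) = -dU/dz` (kJ/mol/nm) and an optional periodic length.  When
#' `force` is omitted it is taken as the negative central-difference
#' gradient of `energy`.  A supplied force is validated against that
#' gradient on a test grid; periodicity of `energy` is validated as well.
#'
#' @param energy vectorised function of z returning kJ/mol.
#' @param force optional vectorised function of z returning kJ/mol/nm.
#' @param periodic_length periodic length in nm, or `NULL` for an aperiodic
#'   coordinate.
#' @param domain for aperiodic potentials, the interval on which the force
#'   is tabulated for simulation (defaults to `c(-10, 10)` nm).
#' @return an object of class `potential_1d`.
#' @examples
#' dw <- periodic_wells_potential(barrier = 10, n_wells = 2, length = 5)
#' dw$energy(1.25)
#' @export
potential_1d <- function(energy, force = NULL, periodic_length = NULL,
                         domain = c(-10, 10)) {
  stopifnot(is.function(energy))
  if (!is.null(periodic_length)) {
    stopifnot(is.numeric(periodic_length), periodic_length > 0)
    domain <- c(0, periodic_length)
  }
  h <- 1e-6 * diff(domain)
  num_force <- function(z) -(energy(z + h) - energy(z - h)) / (2 * h)
  if (is.null(force)) {
    force <- num_force
  } else {
    stopifnot(is.function(force))
    zt <- seq(domain[1] + h, domain[2] - h, length.out = 101)
    fa <- force(zt); fn <- num_force(zt)
    scale <- max(abs(fa), 1)
    if (max(abs(fa - fn)) > 1e-6 * scale)
      stop("supplied force is not the negative gradient of the energy ",
           "(max deviation ", signif(max(abs(fa - fn)), 3), " kJ/mol/nm)")
  }
  if (!is.null(periodic_length)) {
    zt <- seq(0, periodic_length, length.out = 17)
    if (max(abs(energy(zt) - energy(zt + periodic_length))) >
        1e-8 * max(abs(energy(zt)), 1))
      stop("energy is not periodic with the declared periodic_length")
  }
  structure(list(energy = energy, force = force,
                 periodic_length = periodic_length, domain = domain),
            class = "potential_1d")
}

#' @export
print.potential_1d <- function(x, ...) {
  cat("1-D potential:",
      if (is.null(x$periodic_length)) "aperiodic"
      else paste0("periodic, L = ", x$periodic_length, " nm"), "\n")
  invisible(x)
}

#' Flat potential
#'
#' `U(z) = 0` everywhere; the free-diffusion null case.
#'
#' @inheritParams potential_1d
#' @return a `potential_1d`.
#' @export
flat_potential <- function(periodic_length = NULL, domain = c(-10, 10)) {
  potential_1d(function(z) rep(0, length(z)),
               force = function(z) rep(0, length(z)),
               periodic_length = periodic_length, domain = domain)
}

#' Periodic sinusoidal well/barrier potential
#'
#' `U(z) = barrier * sin^2(n_wells * pi * z / length)`: a smooth periodic
#' potential with `n_wells` equally deep wells (at the zeros) separated by
#' barriers of the stated height.  `n_wells = 2` gives the cyclic
#' double-well used in recovery tests.
#'
#' @param barrier barrier height in kJ/mol.
#' @param n_wells number of wells per period.
#' @param length periodic length in nm.
#' @return a `potential_1d`.
#' @export
periodic_wells_potential <- function(barrier, n_wells = 1, length) {
  stopifnot(barrier >= 0, n_wells >= 1, length > 0)
  w <- n_wells * pi / length
  potential_1d(function(z) barrier * sin(w * z)^2,
               force = function(z) -barrier * w * sin(2 * w * z),
               periodic_length = length)
}

#' Periodic Gaussian-well potential
#'
#' A periodic potential that is flat except for Gaussian wells, so that a
#' genuine bulk (zero-energy) region exists; used for end-to-end binding
#' tests.  Wells at positions `centers` (nm) with depths `depths` (kJ/mol,
#' positive = attractive) and common width `sigma` (nm).  Images one period
#' to either side are included so the profile is smooth across the seam.
#'
#' @param centers well centers in nm within `[0, length)`.
#' @param depths well depths in kJ/mol (positive values are wells).
#' @param sigma Gaussian width in nm.
#' @param length periodic length in nm.
#' @return a `potential_1d`.
#' @export
gaussian_wells_potential <- function(centers, depths, sigma, length) {
  stopifnot(length(centers) == length(depths), sigma > 0, length > 0)
  U <- function(z) {
    out <- numeric(base::length(z))
    for (i in seq_along(centers)) {
      for (img in c(-length, 0, length)) {
        d <- z - (centers[i] + img)
        out <- out - depths[i] * exp(-d^2 / (2 * sigma^2))
      }
    }
    out
  }
  Fz <- function(z) {
    out <- numeric(base::length(z))
    for (i in seq_along(centers)) {
      for (img in c(-length, 0, length)) {
        d <- z - (centers[i] + img)
        out <- out - depths[i] * (d / sigma^2) * exp(-d^2 / (2 * sigma^2))
      }
    }
    out
  }
  potential_1d(U, force = Fz, periodic_length = length)
}
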