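#' Brownian-dynamics simulation parameters
#'
#' Parameter record for the overdamped Langevin generator.  Units:
#' `diffusion` nm^2/ns, `dt` ns, `temperature` K, `box_length` nm, `field`
#' V/nm, `charge` elementary charges.  The thermal energy kT (kJ/mol) is
#' derived from the temperature.
#'
#' @param diffusion diffusion coefficient D in nm^2/ns (generic ion in
#'   water at 300 K is of order 1-2).
#' @param dt integration time step in ns.
#' @param n_steps number of integration steps.
#' @param temperature temperature in K.
#' @param seed integer seed, or `NULL` to leave the RNG state alone.
#' @param box_length axial box length L in nm (the default is the study
#'   box, 14.626 nm).
#' @param field constant axial electric field E in V/nm (0 for none).
#' @param charge ion charge q in elementary charges.
#' @return an object of class `sim_params`.
#' @examples
#' sim_params(n_steps = 1000, seed = 1)
#' @export
sim_params <- function(diffusion = 1.0, dt = 1e-3, n_steps,
                       temperature = 300, seed = NULL,
                       box_length = 14.626, field = 0, charge = 1) {
  stopifnot(diffusion >= 0, dt > 0, n_steps >= 1, temperature > 0,
            box_length > 0)
  structure(list(diffusion = diffusion, dt = dt,
                 n_steps = as.integer(n_steps),
                 temperature = temperature, kT = thermal_energy(temperature),
                 seed = seed, box_length = box_length,
                 field = field, charge = charge),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "BD parameters: D = %g nm^2/ns, dt = %g ns, %d steps, T = %g K\n",
    x$diffusion, x$dt, x$n_steps, x$temperature))
  cat(sprintf("  box L = %g nm, field E = %g V/nm, charge q = %+g e\n",
              x$box_length, x$field, x$charge))
  invisible(x)
}

#' Step-shaped compartment restraint
#'
#' A repulsive force of constant magnitude confined to a narrow transition
#' region around a boundary plane (typically the periodic box face).  Ions
#' inside the transition region are pushed away from the boundary into
#' their current compartment; the force is zero elsewhere.  This keeps
#' restrained species in their compartment and maintains asymmetric
#' concentrations across a single membrane in a periodic box.
#'
#' @param boundary_position boundary plane position in nm.
#' @param transition_half_width half-width of the transition region in nm.
#' @param force_magnitude restraining force in kJ/mol/nm; the study value
#'   is 10000.
#' @param species character vector of restrained species tags.
#' @return an object of class `step_restraint`.
#' @export
step_restraint <- function(boundary_position = 0,
                           transition_half_width = 0.1,
                           force_magnitude = 10000,
                           species = "cation") {
  stopifnot(transition_half_width > 0, force_magnitude >= 0)
  structure(list(boundary_position = boundary_position,
                 transition_half_width = transition_half_width,
                 force_magnitude = force_magnitude,
                 species = species),
            class = "step_restraint")
}

#' Synthetic branching channel geometry
#'
#' Idealised tetrameric channel used by the permeation generator and the
#' exit-pathway classifier.  The channel axis is the z axis, luminal side
#' negative and cytoplasmic side positive.  Above the second free-energy
#' basin (`z_basin2`) the channel splits: ions may continue axially to
#' beyond `z_top`, enter one of the inter-protomer clefts (radius beyond
#' `r_cleft`), and from a cleft either rejoin the axial exit or leave
#' laterally past `r_lateral`.
#'
#' @param z_lumen luminal pore entrance in nm (trajectories start below).
#' @param z_basin2 axial position of the branching point in nm (the second
#'   main free-energy basin).
#' @param z_top cytoplasmic top of the pore region in nm.
#' @param r_cleft radial distance marking cleft entry in nm.
#' @param r_lateral radial distance marking a committed lateral exit in nm.
#' @param pore_radius_function positive function R_wall(z) in nm.
#' @param n_clefts number of inter-protomer clefts (4 for a tetramer).
#' @return an object of class `channel_geometry`.
#' @examples
#' channel_geometry()
#' @export
channel_geometry <- function(z_lumen = -2, z_basin2 = 1, z_top = 3,
                             r_cleft = 1, r_lateral = 2.5,
                             pore_radius_function = function(z)
                               0.4 + 0.15 * z^2,
                             n_clefts = 4) {
  if (!(z_lumen < z_basin2 && z_basin2 < z_top))
    stop("geometry invariant violated: need z_lumen < z_basin2 < z_top")
  if (!(r_cleft < r_lateral))
    stop("geometry invariant violated: need r_cleft < r_lateral")
  zt <- seq(z_lumen - 2, z_top + 2, length.out = 101)
  if (any(pore_radius_function(zt) <= 0))
    stop("geometry invariant violated: pore_radius_function must be > 0")
  structure(list(z_lumen = z_lumen, z_basin2 = z_basin2, z_top = z_top,
                 r_cleft = r_cleft, r_lateral = r_lateral,
                 pore_radius_function = pore_radius_function,
                 n_clefts = n_clefts),
            class = "channel_geometry")
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf(
    "channel geometry: z_lumen = %g, z_basin2 = %g, z_top = %g nm\n",
    x$z_lumen, x$z_basin2, x$z_top))
  cat(sprintf("  r_cleft = %g nm, r_lateral = %g nm, %d clefts\n",
              x$r_cleft, x$r_lateral, x$n_clefts))
  invisible(x)
}
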