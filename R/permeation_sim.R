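# Synthetic permeation trajectories through a branching channel geometry,
# with known exit-mode labels.  Paths are scripted guided random walks:
# the axial coordinate follows a mode-specific schedule with Brownian
# noise and the radial coordinate executes the cleft/lateral excursions
# that define each exit mode.  This reproduces the statistics the
# classifier consumes without simulating the full 3-D energy landscape.

# Exit-mode probabilities as a function of axial drift velocity.  At the
# reference drift (the 0.3 V operating point of the default parameters)
# the split is 53/25/17/5 (A/B/C/unclassified); the non-axial share
# decays exponentially with increasing drift, calibrated so that ~80% of
# trajectories exit axially at the 1 V drift.  Monotone increasing in E.
.pathway_probs_from_drift <- function(v, base = c(A = 0.53, B = 0.25,
                                                  C = 0.17,
                                                  unclassified = 0.05),
                                      v_ref = 0.7934, v_scale = 2.167) {
  q_ref <- 1 - base[["A"]]
  q <- min(0.9, q_ref * exp(-(v - v_ref) / v_scale))
  rest <- base[c("B", "C", "unclassified")]
  c(A = 1 - q, q * rest / sum(rest))
}

#' Generate a labelled synthetic permeation ensemble
#'
#' Produces `n_ions` pore-passing 3-D trajectories through a
#' [channel_geometry()], each exiting by an assigned mode -- A (stays
#' axial through `z_top`), B (enters a cleft, then exits axially), C
#' (enters a cleft and leaves laterally past `r_lateral`) -- or by the
#' ambiguous recrossing pattern that exercises the classifier's
#' "unclassified" branch.  Ground-truth labels are stored on each
#' trajectory and on the ensemble.
#'
#' When `pathway_fractions` is `NULL` the mode probabilities are derived
#' from the axial drift implied by `params` (field, charge, diffusion):
#' stronger fields bias ions toward the central axial exit.
#'
#' @param geometry a [channel_geometry()].
#' @param params a [sim_params()]; `dt`, `diffusion`, `field`, `charge`
#'   and `seed` are used.
#' @param pathway_fractions `c(pA, pB, pC)` with sum <= 1; the remainder
#'   generates ambiguous trajectories.  `NULL` derives the fractions
#'   from the drift.
#' @param n_ions number of trajectories (0 gives an empty ensemble).
#' @param n_frames frames per trajectory.
#' @return list of [ion_trajectory()] objects (class
#'   `permeation_ensemble`), each with attribute `label`; ensemble
#'   attribute `labels` is the ground-truth factor.
#' @examples
#' ens <- generate_permeation_ensemble(channel_geometry(),
#'   sim_params(n_steps = 1, seed = 7), c(1, 0, 0), n_ions = 3)
#' attr(ens, "labels")
#' @export
generate_permeation_ensemble <- function(geometry, params,
                                         pathway_fractions = NULL,
                                         n_ions, n_frames = 600) {
  stopifnot(inherits(geometry, "channel_geometry"), n_ions >= 0,
            n_frames >= 50)
  if (!is.null(pathway_fractions)) {
    stopifnot(length(pathway_fractions) == 3,
              all(pathway_fractions >= 0),
              sum(pathway_fractions) <= 1 + 1e-12)
    probs <- c(pathway_fractions,
               max(0, 1 - sum(pathway_fractions)))
  } else {
    v <- (1 / params$kT) * params$diffusion * params$charge *
      params$field * .eV_kJmol
    probs <- .pathway_probs_from_drift(v)
  }
  names(probs) <- .pathway_levels

  if (n_ions == 0)
    return(structure(list(), class = c("permeation_ensemble", "list"),
                     labels = factor(character(0),
                                     levels = .pathway_levels)))

  if (!is.null(params$seed)) set.seed(params$seed)
  modes <- sample(.pathway_levels, n_ions, replace = TRUE, prob = probs)
  dt_out <- params$dt
  trajs <- lapply(seq_len(n_ions), function(i)
    .scripted_trajectory(i, modes[i], geometry, params, n_frames,
                         dt_out))
  structure(trajs, class = c("permeation_ensemble", "list"),
            labels = factor(modes, levels = .pathway_levels),
            probabilities = probs)
}

# One scripted trajectory.  Margins keep the stochastic jitter well away
# from the classification thresholds so that ground-truth labels are
# recoverable (target: > 95% agreement, not certainty).
.scripted_trajectory <- function(ion_id, mode, g, params, n_f, dt_out) {
  band_lo <- g$z_basin2; band_hi <- g$z_top
  band_w <- band_hi - band_lo
  cleft_w <- g$r_lateral - g$r_cleft
  z_start <- g$z_lumen - 1.0
  z_end <- band_hi + 0.5 * band_w + 1.0
  sd_z <- 0.02 * band_w
  sd_r <- 0.06 * cleft_w
  tt <- seq_len(n_f) / n_f          # progress variable in (0, 1]

  ramp <- function(t0, t1, from, to) {
    s <- pmin(1, pmax(0, (tt - t0) / (t1 - t0)))
    from + (to - from) * s
  }
  r_axial <- abs(rnorm(n_f, 0, 0.2 * g$r_cleft))
  r_mid_cleft <- g$r_cleft + 0.5 * cleft_w

  if (mode == "A") {
    z <- ramp(0, 0.9, z_start, z_end)
    r <- pmin(r_axial, 0.75 * g$r_cleft)
  } else if (mode == "B") {
    z <- ramp(0, 0.45, z_start, band_lo + 0.5 * band_w)
    z <- z + ramp(0.55, 0.9, 0, z_end - (band_lo + 0.5 * band_w))
    r <- ramp(0.4, 0.5, 0, 1) * (r_mid_cleft) +
      (1 - ramp(0.4, 0.5, 0, 1)) * pmin(r_axial, 0.75 * g$r_cleft)
  } else if (mode == "C") {
    z <- ramp(0, 0.45, z_start, band_lo + 0.5 * band_w)
    r <- ramp(0.4, 0.5, 0, 1) * r_mid_cleft +
      (1 - ramp(0.4, 0.5, 0, 1)) * pmin(r_axial, 0.75 * g$r_cleft)
    r <- r + ramp(0.7, 0.95, 0, (g$r_lateral - r_mid_cleft) +
                    0.5 * cleft_w + 0.5)
  } else {  # ambiguous: repeated cleft recrossings, ends inside cleft
    z <- ramp(0, 0.45, z_start, band_lo + 0.5 * band_w)
    osc <- 0.5 * (1 - cos(2 * pi * 3 * pmax(0, tt - 0.45) / 0.55))
    r <- pmin(r_axial, 0.75 * g$r_cleft) * (1 - ramp(0.45, 0.5, 0, 1)) +
      ramp(0.45, 0.5, 0, 1) * (g$r_cleft - 0.3 * cleft_w +
                                 osc * 0.9 * cleft_w)
    r[n_f] <- r_mid_cleft
  }
  z <- z + rnorm(n_f, 0, sd_z)
  r <- pmax(0, r + rnorm(n_f, 0, sd_r))
  # keep the jitter from faking a pathway: clamp C/ambiguous below z_top
  if (mode %in% c("C", "unclassified"))
    z <- pmin(z, band_hi - 0.05 * band_w)
  # ensure the scripted start/end land where the mode demands
  z[1] <- z_start
  if (mode %in% c("A", "B")) z[n_f] <- max(z[n_f], z_end)

  phi <- runif(1, 0, 2 * pi) + cumsum(rnorm(n_f, 0, 0.02))
  pos <- cbind(x = r * cos(phi), y = r * sin(phi), z = z)
  tr <- ion_trajectory(ion_id = ion_id, times = seq_len(n_f) * dt_out,
                       positions = pos,
                       box = c(4 * g$r_lateral, 4 * g$r_lateral,
                               max(params$box_length,
                                   z_end - z_start + 2)),
                       charge = params$charge, wrapped = FALSE)
  attr(tr, "label") <- mode
  tr
}

#' Homogeneous Poisson solvent cloud
#'
#' Uniform random points in a box, with count drawn from
#' `Poisson(density * volume)`; a stand-in for bulk water oxygen
#' positions in hydration and pore-radius tests (bulk water is about
#' 33.4 molecules/nm^3).
#'
#' @param density points per nm^3 (>= 0).
#' @param box box lengths `c(Lx, Ly, Lz)` in nm.
#' @param seed integer seed or `NULL`.
#' @return n x 3 matrix of points; attribute `density` and `box`.
#' @examples
#' nrow(generate_solvent_cloud(33.4, c(2, 2, 2), seed = 1))
#' @export
generate_solvent_cloud <- function(density, box, seed = NULL) {
  stopifnot(density >= 0, length(box) == 3, all(box > 0))
  if (!is.null(seed)) set.seed(seed)
  n <- rpois(1, density * prod(box))
  pts <- cbind(x = runif(n, 0, box[1]), y = runif(n, 0, box[2]),
               z = runif(n, 0, box[3]))
  attr(pts, "density") <- density
  attr(pts, "box") <- box
  pts
}
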