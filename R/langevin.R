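# Overdamped Langevin (Brownian dynamics) generator.  The compiled core
# integrates independent walkers; wrappers here build the force grid from a
# potential_1d, check the step quality and handle seeding.

.force_grid <- function(potential, n_grid = 4096) {
  if (is.null(potential)) return(list(x = numeric(0), f = numeric(0)))
  L <- potential$periodic_length
  if (!is.null(L)) {
    x <- seq(0, L, length.out = n_grid + 1)
    f <- potential$force(x)
    f[n_grid + 1] <- f[1]  # enforce exact periodicity at the seam
  } else {
    x <- seq(potential$domain[1], potential$domain[2], length.out = n_grid)
    f <- potential$force(x)
  }
  if (all(f == 0)) return(list(x = numeric(0), f = numeric(0)))
  list(x = x, f = f)
}

.check_step_quality <- function(f_max, params, bias_k = 0) {
  beta <- 1 / params$kT
  drift <- beta * f_max * params$diffusion * params$dt
  if (drift > 0.05)
    warning(sprintf(paste0(
      "step quality: beta*F_max*D*dt = %.3g nm per step; the overdamped ",
      "update assumes this is small -- consider reducing dt"), drift))
  if (bias_k > 0) {
    theta <- beta * params$diffusion * bias_k * params$dt
    if (theta > 0.25)
      warning(sprintf(paste0(
        "step quality: beta*D*k*dt = %.3g for the harmonic bias; sampled ",
        "variance will exceed kT/k by ~%.0f%% -- consider reducing dt"),
        theta, 100 * theta / 2))
  }
  invisible(NULL)
}

.field_force <- function(params) params$charge * params$field * .eV_kJmol

#' Simulate a 1-D overdamped Langevin trajectory
#'
#' Euler-Maruyama integration of `z' = z + beta*D*F(z)*dt +
#' sqrt(2*D*dt)*eta` with `eta ~ N(0,1)`.  The total force is the
#' potential force plus the constant field force `q*E` (converted to
#' kJ/mol/nm), an optional harmonic bias `-k*(z - center)` (minimum-image
#' displacement when periodic) and an optional step restraint.  Periodic
#' coordinates are wrapped into `[0, L)`.  The stationary distribution of
#' the exact dynamics is `exp(-U_total/kT)`.
#'
#' A step whose deterministic-plus-noise displacement exceeds half the
#' periodic box aborts with a time-step diagnostic.  The dimensionless
#' step quality `beta*F_max*D*dt` is checked and warned on.
#'
#' @param potential a [potential_1d()]; `NULL` means flat.
#' @param params a [sim_params()].
#' @param bias optional harmonic bias, `list(center =, k =)` with `k` in
#'   kJ/mol/nm^2.
#' @param restraint optional [step_restraint()].
#' @param z0 starting position in nm (default: bias center if biased, else
#'   mid-box).
#' @param sample_every record every this-many steps (default 1).
#' @param periodic logical; simulate with periodic boundaries on
#'   `[0, box_length)`.  Defaults to `TRUE` when the potential is periodic.
#' @return numeric vector of sampled positions (nm), of length
#'   `floor(n_steps / sample_every)`; attributes `dt_sample` (ns) and
#'   `params`.
#' @examples
#' p <- sim_params(n_steps = 2000, dt = 1e-4, seed = 1)
#' z <- simulate_langevin_1d(flat_potential(), p,
#'                           bias = list(center = 0, k = 500))
#' var(z)  # ~ kT/k
#' @export
simulate_langevin_1d <- function(potential = NULL, params, bias = NULL,
                                 restraint = NULL, z0 = NULL,
                                 sample_every = 1, periodic = NULL) {
  out <- .bd_run(potential, params,
                 z0 = z0, bias_centers = if (!is.null(bias)) bias$center,
                 bias_k = if (!is.null(bias)) bias$k else 0,
                 restraint = restraint, sample_every = sample_every,
                 periodic = periodic)
  z <- out$z[, 1]
  attr(z, "dt_sample") <- params$dt * sample_every
  attr(z, "params") <- params
  z
}

# Multi-walker core shared by the umbrella and permeation generators.
# bias_centers: NULL or one center per walker (scalar recycled via z0).
.bd_run <- function(potential, params, z0 = NULL, bias_centers = NULL,
                    bias_k = 0, restraint = NULL, sample_every = 1,
                    n_walkers = NULL, periodic = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(periodic))
    periodic <- !is.null(potential) && !is.null(potential$periodic_length)
  L <- if (periodic) {
    if (!is.null(potential) && !is.null(potential$periodic_length))
      potential$periodic_length else params$box_length
  } else -1
  if (!is.null(bias_centers)) {
    n_walkers <- length(bias_centers)
  } else if (is.null(n_walkers)) {
    n_walkers <- if (is.null(z0)) 1L else length(z0)
  }
  if (is.null(z0)) {
    z0 <- if (!is.null(bias_centers)) bias_centers
          else rep(if (periodic) L / 2 else 0, n_walkers)
  }
  z0 <- rep_len(z0, n_walkers)
  if (periodic) z0 <- z0 %% L

  grid <- .force_grid(potential)
  fmax <- max(abs(c(grid$f, 0))) + abs(.field_force(params)) +
    if (!is.null(restraint)) restraint$force_magnitude else 0
  .check_step_quality(fmax, params, bias_k)

  if (!is.null(params$seed)) set.seed(params$seed)
  z <- bd_simulate_cpp(
    z0 = z0, n_steps = params$n_steps, dt = params$dt,
    D = params$diffusion, kT = params$kT,
    grid_x = grid$x, grid_f = grid$f,
    periodic_L = L,
    bias_center = if (!is.null(bias_centers)) as.numeric(bias_centers)
                  else numeric(0),
    bias_k = bias_k,
    field_force = .field_force(params),
    restraint_boundary = if (!is.null(restraint))
      restraint$boundary_position else 0,
    restraint_halfwidth = if (!is.null(restraint))
      restraint$transition_half_width else 0,
    restraint_force = if (!is.null(restraint))
      restraint$force_magnitude else 0,
    has_restraint = !is.null(restraint),
    sample_every = as.integer(sample_every))
  list(z = z, L = if (periodic) L else NULL)
}

#' Simulate an applied-field permeation ensemble on a flat landscape
#'
#' Runs `n_ions` independent Brownian walkers in a periodic box under a
#' constant axial field (and optional axial potential / step restraint),
#' with free lateral diffusion, and returns wrapped 3-D trajectories
#' suitable for crossing counting and current analysis.
#'
#' @param params a [sim_params()]; `field` and `charge` set the drift.
#' @param n_ions number of ions.
#' @param potential optional axial [potential_1d()] (periodic).
#' @param restraint optional [step_restraint()].
#' @param sample_every record every this-many steps.
#' @param box_xy lateral box lengths in nm.
#' @return a list of [ion_trajectory()] objects.
#' @export
simulate_field_ensemble <- function(params, n_ions, potential = NULL,
                                    restraint = NULL, sample_every = 10,
                                    box_xy = c(10, 10)) {
  stopifnot(n_ions >= 1)
  if (!is.null(params$seed)) set.seed(params$seed)
  p2 <- params; p2$seed <- NULL  # RNG already seeded once for the ensemble
  z0 <- runif(n_ions, 0, params$box_length)
  run <- .bd_run(potential, p2, z0 = z0, restraint = restraint,
                 sample_every = sample_every, periodic = TRUE)
  n_f <- nrow(run$z)
  times <- seq_len(n_f) * params$dt * sample_every
  sig_f <- sqrt(2 * params$diffusion * params$dt * sample_every)
  lapply(seq_len(n_ions), function(i) {
    xy <- apply(matrix(rnorm(2 * n_f, sd = sig_f), ncol = 2), 2, cumsum)
    ion_trajectory(ion_id = i, times = times,
                   positions = cbind(x = xy[, 1] %% box_xy[1],
                                     y = xy[, 2] %% box_xy[2],
                                     z = run$z[, i]),
                   box = c(box_xy, params$box_length),
                   charge = params$charge, wrapped = TRUE)
  })
}
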