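# Brownian-dynamics generator: stationary statistics, drift, restraint
# containment, umbrella layout, point clouds, determinism.

test_that("potential_1d validates force consistency and periodicity", {
  expect_s3_class(periodic_wells_potential(10, 2, 5), "potential_1d")
  expect_error(potential_1d(function(z) z^2,
                            force = function(z) z,  # wrong sign
                            domain = c(-1, 1)),
               "negative gradient")
  expect_error(potential_1d(function(z) z, periodic_length = 2),
               "not periodic")
  # numerical force from energy alone matches analytic
  p <- potential_1d(function(z) 3 * z^2, domain = c(-2, 2))
  expect_equal(p$force(0.7), -6 * 0.7, tolerance = 1e-6)
})

test_that("no noise and no force leaves the walker at its start", {
  p <- sim_params(diffusion = 0, dt = 1e-3, n_steps = 500, seed = 1)
  z <- simulate_langevin_1d(NULL, p, z0 = 2.25)
  expect_length(z, 500)
  expect_true(all(z == 2.25))
})

test_that("biased flat-potential variance obeys equipartition kT/k", {
  kT <- thermal_energy(300)
  for (k in c(100, 500, 1000)) {
    dt <- 0.02 * kT / k   # beta*D*k*dt = 0.02: discretisation bias ~1%
    p <- sim_params(diffusion = 1, dt = dt, n_steps = 3e5, seed = k)
    z <- simulate_langevin_1d(flat_potential(), p,
                              bias = list(center = 0, k = k))
    expect_equal(var(z), kT / k, tolerance = 0.05)
  }
})

test_that("drift velocity in a field matches beta*D*q*E mobility", {
  kT <- thermal_energy(300)
  p <- sim_params(diffusion = 1, dt = 1e-3, n_steps = 1e6,
                  field = 0.1, charge = 1, seed = 2)
  z <- simulate_langevin_1d(NULL, p, periodic = TRUE)
  zu <- permeon:::.unwrap(z, p$box_length)
  v <- (zu[length(zu)] - zu[1]) / (p$n_steps * p$dt)
  v_theory <- (1 / kT) * 1 * 1 * 0.1 * 96.485332
  expect_equal(v, v_theory, tolerance = 0.05)
})

test_that("measured diffusion from MSD matches the input D", {
  p <- sim_params(diffusion = 1.4, dt = 1e-3, n_steps = 4e5, seed = 3)
  z <- simulate_langevin_1d(NULL, p, periodic = FALSE)
  for (lag in c(1, 10, 100)) {
    msd <- mean(diff(z, lag = lag)^2)
    expect_equal(msd / (2 * lag * p$dt), 1.4, tolerance = 0.05)
  }
})

test_that("divergent steps abort with a time-step diagnostic", {
  # enormous force over a periodic box: one step exceeds L/2
  pot <- potential_1d(function(z) 1e6 * sin(2 * pi * z / 2)^2,
                      periodic_length = 2)
  p <- sim_params(diffusion = 1, dt = 1e-2, n_steps = 100, seed = 4)
  expect_error(suppressWarnings(simulate_langevin_1d(pot, p)),
               "reduce the time step")
})

test_that("step quality warnings fire on coarse time steps", {
  p <- sim_params(diffusion = 1, dt = 5e-3, n_steps = 100, seed = 5)
  expect_warning(simulate_langevin_1d(flat_potential(), p,
                                      bias = list(center = 0, k = 500)),
                 "step quality")
})

test_that("step restraint of 10000 kJ/mol/nm confines ions completely", {
  res <- step_restraint(boundary_position = 0,
                        transition_half_width = 0.1,
                        force_magnitude = 10000)
  p <- sim_params(diffusion = 1, dt = 1e-5, n_steps = 1e6,
                  box_length = 5, seed = 6)
  z <- simulate_langevin_1d(flat_potential(periodic_length = 5), p,
                            restraint = res, z0 = 2.5)
  zu <- permeon:::.unwrap(z, 5)
  crossings <- sum(diff(floor(zu / 5)) != 0)
  expect_identical(crossings, 0L)
})

test_that("identical seeds give identical trajectories", {
  p <- sim_params(diffusion = 1, dt = 1e-3, n_steps = 2000, seed = 7)
  z1 <- simulate_langevin_1d(flat_potential(), p,
                             bias = list(center = 0, k = 200))
  z2 <- simulate_langevin_1d(flat_potential(), p,
                             bias = list(center = 0, k = 200))
  expect_identical(as.numeric(z1), as.numeric(z2))
})

test_that("umbrella layout spans the study box within one spacing", {
  pot <- flat_potential(periodic_length = 14.626)
  ws <- suppressWarnings(generate_umbrella_dataset(
    pot, n_windows = 209, spacing = 0.07, k = 500,
    params = sim_params(n_steps = 60, dt = 1e-4,
                        box_length = 14.626, seed = 8),
    check_overlap = FALSE))
  expect_length(ws, 209)
  centers <- vapply(ws, `[[`, numeric(1), "center")
  expect_true(all(centers >= 0 & centers < 14.626))
  # unwrapped span 208 * 0.07 = 14.56; wrap overhang under one spacing
  expect_lt(209 * 0.07 - 14.626, 0.07)
  # one more window than fits errors
  expect_error(generate_umbrella_dataset(
    pot, n_windows = 211, spacing = 0.07, k = 500,
    params = sim_params(n_steps = 60, dt = 1e-4, seed = 8)),
    "overrun")
})

test_that("umbrella windows carry retained samples and in-plane data", {
  pot <- periodic_wells_potential(5, 1, 4)
  ws <- generate_umbrella_dataset(pot, n_windows = 21, spacing = 4 / 21,
          k = 500, params = sim_params(n_steps = 1200, dt = 2e-4,
                                       box_length = 4, seed = 9),
          perp_spread = c(0.8, 1.5))
  w <- ws[[5]]
  expect_length(w$samples, 1200)
  expect_length(retained_samples(w), 1000)  # 1/6 discarded
  expect_equal(dim(w$perp_samples), c(1200, 2))
  expect_equal(sd(w$perp_samples[, 2]), 1.5, tolerance = 0.1)
})

test_that("non-overlapping neighbor windows trigger a warning", {
  pot <- flat_potential(periodic_length = 10)
  expect_warning(generate_umbrella_dataset(
    pot, n_windows = 4, spacing = 2.5, k = 5000,
    params = sim_params(n_steps = 600, dt = 1e-4, box_length = 10,
                        seed = 10)),
    "non-overlapping")
})

test_that("labelled permeation ensembles honor requested fractions", {
  geom <- channel_geometry()
  # degenerate mixture: every trajectory axial
  ens <- generate_permeation_ensemble(
    geom, sim_params(n_steps = 1, dt = 0.01, seed = 11),
    pathway_fractions = c(1, 0, 0), n_ions = 12)
  expect_true(all(attr(ens, "labels") == "A"))
  # empty ensemble
  e0 <- generate_permeation_ensemble(
    geom, sim_params(n_steps = 1, dt = 0.01, seed = 11),
    pathway_fractions = c(1, 0, 0), n_ions = 0)
  expect_length(e0, 0)
  # study split: realized counts within exact binomial 99% intervals
  ens <- generate_permeation_ensemble(
    geom, sim_params(n_steps = 1, dt = 0.01, seed = 12),
    pathway_fractions = c(0.53, 0.25, 0.17), n_ions = 400)
  counts <- table(attr(ens, "labels"))
  for (i in seq_along(p <- c(A = 0.53, B = 0.25, C = 0.17,
                             unclassified = 0.05))) {
    lo <- qbinom(0.005, 400, p[i])
    hi <- qbinom(0.995, 400, p[i])
    expect_gte(counts[[names(p)[i]]], lo)
    expect_lte(counts[[names(p)[i]]], hi)
  }
  # every trajectory starts below the lumen and carries its label
  expect_true(all(vapply(ens, function(tr)
    tr$positions[1, 3] < geom$z_lumen, logical(1))))
  expect_identical(as.character(attr(ens, "labels")),
                   vapply(ens, attr, character(1), "label"))
})

test_that("geometry invariants are enforced", {
  expect_error(channel_geometry(z_lumen = 2, z_basin2 = 1),
               "z_lumen < z_basin2")
  expect_error(channel_geometry(r_cleft = 3, r_lateral = 2),
               "r_cleft < r_lateral")
  expect_error(channel_geometry(pore_radius_function = function(z)
    z * 0), "must be > 0")
})

test_that("solvent clouds are Poisson with exact determinism", {
  expect_identical(nrow(generate_solvent_cloud(0, c(2, 2, 2),
                                               seed = 1)), 0L)
  pts <- generate_solvent_cloud(33.4, c(10, 10, 10), seed = 13)
  lambda <- 33.4 * 1000
  expect_lt(abs(nrow(pts) - lambda), 4 * sqrt(lambda))
  expect_true(all(pts >= 0 & pts <= 10))
  expect_identical(pts, generate_solvent_cloud(33.4, c(10, 10, 10),
                                               seed = 13))
})
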