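# Effective sampled area and standard binding free energy.

test_that("effective area recovers 2*pi*xi1*xi2 from samples", {
  set.seed(51)
  # isotropic unit Gaussian: A = 2*pi within 5%
  iso <- effective_area(matrix(rnorm(2e4), ncol = 2))
  expect_equal(iso$area, 2 * pi, tolerance = 0.05)
  # exact eigen-case: sample covariance exactly diag(2, 1)
  a <- sqrt(11 * 2 / 6); b <- sqrt(11 * 1 / 6)
  pts <- rbind(matrix(rep(c(a, 0, -a, 0), 3), ncol = 2, byrow = TRUE),
               matrix(rep(c(0, b, 0, -b), 3), ncol = 2, byrow = TRUE))
  ex <- effective_area(pts)
  expect_equal(sort(ex$eigenvalues), c(1, 2), tolerance = 1e-12)
  expect_equal(ex$area, 2 * pi * sqrt(2), tolerance = 1e-10)
  # correlated Gaussian: rotation-invariant (eigenvalues, not marginals)
  S <- matrix(c(1, 0.9, 0.9, 1), 2)
  X <- matrix(rnorm(4e5), ncol = 2) %*% chol(S)
  expect_equal(effective_area(X)$area, 2 * pi * sqrt(1.9 * 0.1),
               tolerance = 0.05)
  # rotating the samples leaves the area unchanged
  ang <- 0.83
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  expect_equal(effective_area(X %*% R)$area, effective_area(X)$area,
               tolerance = 1e-6)
})

test_that("effective area rejects degenerate or tiny inputs", {
  expect_error(effective_area(matrix(rnorm(8), ncol = 2)),
               "at least 10")
  X <- cbind(rnorm(100), 0)
  expect_error(effective_area(X), "degenerate")
})

test_that("bulk windows pool in-plane samples outside the bound zone", {
  ws <- generate_umbrella_dataset(
    flat_potential(periodic_length = 10), n_windows = 20,
    spacing = 0.5, k = 500,
    params = sim_params(n_steps = 600, dt = 1e-4, box_length = 10,
                        seed = 52),
    perp_spread = c(1, 1), check_overlap = FALSE)
  pooled <- bulk_perp_samples(ws, bulk_interval = c(2, 7))
  centers <- vapply(ws, `[[`, numeric(1), "center")
  n_bulk <- sum(centers < 2 | centers > 7)
  expect_equal(nrow(pooled), n_bulk * 500)  # retained rows only
  expect_error(bulk_perp_samples(ws, c(-1, 11)), "no windows")
})

test_that("square-well dG0 matches closed form and fine quadrature", {
  kT <- thermal_energy(300)
  z <- seq(0, 2, length.out = 4001)
  Wfun <- function(z) ifelse(z >= 0.5 & z <= 1.5, -10, 0)
  pmf <- pmf_profile(z, Wfun(z), reference = "bulk_zero",
                     bulk_interval = c(1.8, 2))
  res <- standard_binding_free_energy(pmf, c(0, 2), area = 1)
  closed <- -kT * log((exp(10 / kT) * 1 + 1) / 1.6606)
  expect_equal(res$dG0, closed, tolerance = 1e-3)
  expect_equal(res$dG0, fine_quadrature_dG0(Wfun, c(0, 2), 1),
               tolerance = 0.01)
})

test_that("flat profile at the standard-state volume gives exactly 0", {
  z <- seq(0, 1, length.out = 101)
  pmf <- pmf_profile(z, rep(0, 101), reference = "bulk_zero",
                     bulk_interval = c(0.9, 1))
  res <- standard_binding_free_energy(pmf, c(0, 1), area = 1.6606)
  expect_equal(res$dG0, 0, tolerance = 1e-12)
  expect_equal(res$boltzmann_integral, 1)
})

test_that("area scaling shifts dG0 by exactly -kT*ln(A/A')", {
  kT <- thermal_energy(300)
  z <- seq(0, 2, length.out = 201)
  W <- -5 * exp(-(z - 1)^2 / 0.08)
  pmf <- pmf_profile(z, W - mean(W[z >= 1.9]),
                     reference = "bulk_zero", bulk_interval = c(1.9, 2))
  g1 <- standard_binding_free_energy(pmf, c(0.5, 1.5), area = 3.09)$dG0
  g2 <- standard_binding_free_energy(pmf, c(0.5, 1.5), area = 6.18)$dG0
  expect_equal(g2 - g1, -kT * log(2), tolerance = 1e-10)
  g3 <- standard_binding_free_energy(pmf, c(0.5, 1.5), area = 9.09)$dG0
  expect_equal(g3 - g1, -kT * log(9.09 / 3.09), tolerance = 1e-10)
})

test_that("deepening the profile never weakens binding", {
  z <- seq(0, 2, length.out = 201)
  W0 <- rep(0, 201)
  pmf0 <- pmf_profile(z, W0, reference = "bulk_zero",
                      bulk_interval = c(1.8, 2))
  g0 <- standard_binding_free_energy(pmf0, c(0.2, 1.2), area = 1)$dG0
  for (bin in c(30, 60, 90)) {
    W <- W0; W[bin] <- -4
    # keep the bulk reference: the deepened bin is inside the bound zone
    pmf <- pmf_profile(z, W, reference = "bulk_zero",
                       bulk_interval = c(1.8, 2))
    g <- standard_binding_free_energy(pmf, c(0.2, 1.2), area = 1)$dG0
    expect_lt(g, g0)
  }
})

test_that("a vanishing bound interval unbinds completely", {
  kT <- thermal_energy(300)
  z <- seq(0, 2, length.out = 201)
  pmf <- pmf_profile(z, rep(0, 201), reference = "bulk_zero",
                     bulk_interval = c(1.8, 2))
  g6 <- standard_binding_free_energy(pmf, c(1, 1 + 1e-6), area = 1)$dG0
  expect_equal(g6, -kT * log(1e-6 / 1.6606), tolerance = 1e-6)
  g9 <- standard_binding_free_energy(pmf, c(1, 1 + 1e-9), area = 1)$dG0
  expect_gt(g9, 50)
  expect_gt(g9, g6)   # diverges as the interval shrinks
})

test_that("contract violations raise informative errors", {
  z <- seq(0, 2, length.out = 51)
  pmf_min <- pmf_profile(z, z * 0 + 1 - 1)  # min_zero reference
  expect_error(standard_binding_free_energy(pmf_min, c(0, 1), 1),
               "bulk_zero")
  pmf <- pmf_profile(z, rep(0, 51), reference = "bulk_zero",
                     bulk_interval = c(1.8, 2))
  expect_error(standard_binding_free_energy(pmf, c(-1, 1), 1),
               "support")
})

test_that("bootstrap errors on W propagate to a dG0 error", {
  set.seed(53)
  z <- seq(0, 2, length.out = 101)
  pmf <- pmf_profile(z, rep(0, 101), errors = rep(0.3, 101),
                     reference = "bulk_zero", bulk_interval = c(1.8, 2))
  res <- standard_binding_free_energy(pmf, c(0, 1), area = 1.6606)
  expect_true(is.finite(res$dG0_error) && res$dG0_error > 0)
})
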