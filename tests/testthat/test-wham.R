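# WHAM reconstruction: limiting cases, symmetries, oracle agreement,
# bootstrap behaviour and extremum reporting.

test_that("zero-bias uniform samples invert to a flat cyclic profile", {
  set.seed(21)
  L <- 5; N <- 50000; n_bins <- 50
  w <- umbrella_window(center = L / 2, k = 1e-9,
                       samples = runif(N, 0, L), discard_fraction = 0)
  pmf <- solve_wham(list(w), n_bins = n_bins, periodic_length = L)
  # multinomial noise scale: kT * sqrt(n_bins / N) per bin
  expect_lt(sd(pmf$W), 2 * thermal_energy(300) * sqrt(n_bins / N))
})

test_that("duplicated windows equal one window with doubled samples", {
  set.seed(22)
  s <- rnorm(3000, 2.0, 0.1)
  w1 <- umbrella_window(2.0, 500, s, discard_fraction = 0)
  w2 <- umbrella_window(2.0, 500, c(s, s), discard_fraction = 0)
  p_dup <- solve_wham(list(w1, w1), n_bins = 40, periodic_length = 4,
                      tol = 1e-10)
  p_one <- solve_wham(list(w2), n_bins = 40, periodic_length = 4,
                      tol = 1e-10)
  expect_equal(p_dup$W, p_one$W, tolerance = 1e-10)
})

test_that("probability mass is conserved and gauge shifts cancel", {
  set.seed(23)
  L <- 4
  pot <- periodic_wells_potential(6, 1, L)
  ws <- generate_umbrella_dataset(pot, n_windows = 21, spacing = L / 21,
          k = 500, params = sim_params(n_steps = 3000, dt = 2e-4,
                                       box_length = L, seed = 23))
  pmf <- solve_wham(ws, n_bins = 80, periodic_length = L)
  expect_equal(sum(pmf$details$p), 1, tolerance = 1e-9)
  # adding a constant c to every window bias multiplies all the bias
  # factors by exp(-c/kT); the unbiased profile must not move
  setup <- permeon:::.wham_setup(ws, 80, 300, L)
  base <- permeon:::.wham_core(setup, setup$counts, setup$N,
                               1e-8, 1e5)
  setup2 <- setup
  setup2$cmat <- setup$cmat * exp(-3.7 / setup$kT)
  shifted <- permeon:::.wham_core(setup2, setup2$counts, setup2$N,
                                  1e-8, 1e5)
  d <- base$W - shifted$W
  expect_lt(max(abs(d - mean(d))), 1e-6)
})

test_that("solver agrees with a naive independent WHAM within 0.1 kJ/mol", {
  L <- 4
  pot <- periodic_wells_potential(8, 2, L)
  for (seed in c(31, 32, 33)) {
    ws <- generate_umbrella_dataset(pot, n_windows = 25,
            spacing = L / 25, k = 500,
            params = sim_params(n_steps = 2500, dt = 2e-4,
                                box_length = L, seed = seed))
    pmf <- solve_wham(ws, n_bins = 60, periodic_length = L,
                      tol = 1e-8)
    ora <- naive_wham(ws, n_bins = 60, L = L, tol = 1e-8)
    d <- pmf$W - ora$W
    expect_lt(max(abs(d - mean(d))), 0.1)
  }
})

test_that("flagged equilibration samples never enter the histograms", {
  set.seed(24)
  junk <- rep(5.0, 500)             # pre-equilibration excursion
  good <- runif(2500, 1.8, 2.2)
  w <- umbrella_window(2.0, 1e-9, c(junk, good),
                       discard_fraction = 500 / 3000)
  pmf <- solve_wham(list(w), n_bins = 40)
  expect_true(all(pmf$bin_centers < 4))  # grid spans retained data only
  # positive control: without the discard, the excursion enters the
  # grid and leaves a coverage gap
  w0 <- umbrella_window(2.0, 1e-9, c(junk, good),
                        discard_fraction = 0)
  expect_error(solve_wham(list(w0), n_bins = 40), "histogram gap")
})

test_that("coverage gaps are reported with their location", {
  set.seed(25)
  w1 <- umbrella_window(1, 500, rnorm(2000, 1, 0.07),
                        discard_fraction = 0)
  w2 <- umbrella_window(5, 500, rnorm(2000, 5, 0.07),
                        discard_fraction = 0)
  expect_error(solve_wham(list(w1, w2), n_bins = 60),
               "histogram gap")
})

test_that("bootstrap errors: degeneracy, scaling, determinism", {
  # degenerate: identical constant samples -> zero error where occupied
  wd <- lapply(1:5, function(i)
    umbrella_window(2, 500, rep(2, 100), discard_fraction = 0))
  pmf_d <- bootstrap_pmf(wd, n_bins = 20, n_boot = 20, seed = 1)
  occ <- is.finite(pmf_d$W)
  expect_true(all(pmf_d$errors[occ] == 0))

  # halving per-window (independent) samples scales the error by
  # ~sqrt(2); windows built from exact Boltzmann draws on a flat
  # landscape so the sample count is the only information budget
  L <- 3
  sigma <- sqrt(thermal_energy(300) / 500)
  centers <- (seq_len(21) - 1) * L / 21
  ratios <- vapply(1:10, function(r) {
    set.seed(40 + r)
    ws_full <- lapply(centers, function(cc)
      umbrella_window(cc, 500,
                      (rnorm(2000, cc, sigma)) %% L,
                      discard_fraction = 0))
    ws_half <- lapply(ws_full, function(w)
      umbrella_window(w$center, w$k, w$samples[1:1000],
                      discard_fraction = 0))
    e_full <- bootstrap_pmf(ws_full, n_bins = 50, periodic_length = L,
                            n_boot = 30, seed = r)$errors
    e_half <- bootstrap_pmf(ws_half, n_bins = 50, periodic_length = L,
                            n_boot = 30, seed = r)$errors
    mean(e_half, na.rm = TRUE) / mean(e_full, na.rm = TRUE)
  }, numeric(1))
  expect_equal(mean(ratios), sqrt(2), tolerance = 0.25)

  # fixed seed reproduces the error vector exactly
  pot <- periodic_wells_potential(4, 1, L)
  ws <- generate_umbrella_dataset(pot, n_windows = 21,
          spacing = L / 21, k = 500,
          params = sim_params(n_steps = 2000, dt = 2e-4,
                              box_length = L, seed = 26))
  e1 <- bootstrap_pmf(ws, n_bins = 50, periodic_length = L,
                      n_boot = 25, seed = 99)$errors
  e2 <- bootstrap_pmf(ws, n_bins = 50, periodic_length = L,
                      n_boot = 25, seed = 99)$errors
  expect_identical(e1, e2)
})

test_that("cyclic profiles join smoothly across the periodic seam", {
  L <- 4
  ws <- generate_umbrella_dataset(flat_potential(periodic_length = L),
          n_windows = 25, spacing = L / 25, k = 500,
          params = sim_params(n_steps = 6000, dt = 2e-4,
                              box_length = L, seed = 27))
  pmf <- solve_wham(ws, n_bins = 80, periodic_length = L)
  seam <- abs(pmf$W[1] - pmf$W[length(pmf$W)])
  fluct <- sd(diff(pmf$W))
  expect_lt(seam, 4 * fluct)
})

test_that("pmf_extremum reports signed wells and barriers", {
  z <- seq(-2, 2, length.out = 81)
  mk <- function(W) pmf_profile(z, W - mean(W[z >= 1.5]),
                                reference = "bulk_zero",
                                bulk_interval = c(1.5, 2))
  # flat profile: zero-magnitude barrier
  ex0 <- pmf_extremum(mk(rep(0, 81)))
  expect_identical(ex0$kind, "barrier")
  expect_identical(ex0$value, 0)
  # single deep well, magnitude echoing a divalent binding profile
  W <- rep(0, 81); W[21] <- -30.9
  ex <- pmf_extremum(mk(W))
  expect_equal(ex$value, -30.9)
  expect_identical(ex$kind, "well")
  expect_equal(ex$z, z[21])
  # purely repulsive square barrier (anion-style profile)
  Wb <- rep(0, 81); Wb[z > -0.5 & z < 0.5] <- 25.9
  exb <- pmf_extremum(mk(Wb))
  expect_equal(exb$value, 25.9)
  expect_identical(exb$kind, "barrier")
  # exact ties break toward the smallest |z|
  Wt <- rep(0, 81)
  Wt[c(which.min(abs(z + 1)), which.min(abs(z - 0.5)))] <- -7
  expect_equal(pmf_extremum(mk(Wt))$z, 0.5, tolerance = 1e-9)
  # reference and interval contracts
  expect_error(pmf_extremum(pmf_profile(z, W)), "bulk_zero")
  expect_error(pmf_extremum(mk(W), search_interval = c(10, 11)),
               "empty")
})
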