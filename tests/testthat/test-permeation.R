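# Field-voltage conversion, periodic-boundary crossings, currents and
# the IV fit.

test_that("voltage is the field-box product", {
  expect_identical(voltage_from_field(0, 14.626), 0)
  expect_equal(voltage_from_field(0.3 / 14.626, 14.626), 0.3)
  expect_equal(field_from_voltage(1.0, 14.626), 0.068371,
               tolerance = 1e-5)
  expect_equal(voltage_from_field(field_from_voltage(0.5)), 0.5)
})

test_that("monotone rise through two box lengths gives two crossings", {
  Lz <- 10
  z <- seq(0.5, 0.5 + 2 * Lz, length.out = 500) %% Lz
  tr <- ion_trajectory(1, seq_len(500) * 0.01, cbind(0, 0, z),
                       c(5, 5, Lz), wrapped = TRUE)
  ev <- detect_crossings(tr, boundary_z = 0, discard = 0)
  expect_identical(nrow(ev), 2L)
  expect_true(all(ev$direction == 1))
  # stationary ion: no events
  tr0 <- ion_trajectory(2, 1:100, cbind(0, 0, rep(3, 100)),
                        c(5, 5, Lz))
  expect_identical(nrow(detect_crossings(tr0, discard = 0)), 0L)
})

test_that("net crossings equal the independent unwrap oracle exactly", {
  set.seed(61)
  for (i in 1:100) {
    L <- runif(1, 2, 10)
    walk <- make_wrapped_walk(1500, L, drift = runif(1, -0.3, 0.3),
                              sd_step = 0.25)
    tr <- ion_trajectory(i, seq_len(1500) * 0.01,
                         cbind(0, 0, walk$zw), c(5, 5, L),
                         wrapped = TRUE)
    ev <- detect_crossings(tr, boundary_z = 0, discard = 0)
    oracle <- floor(walk$zu[1500] / L) - floor(walk$zu[1] / L)
    expect_equal(sum(ev$direction), oracle)
  }
})

test_that("coarse frames raise an unwrap-ambiguity error", {
  z <- c(0.1, 2.5, 0.2)   # jumps of ~Lz/2: direction is ambiguous
  tr <- ion_trajectory(1, 1:3, cbind(0, 0, z), c(5, 5, 5))
  expect_error(detect_crossings(tr, discard = 0), "unwrap ambiguity")
  zu <- c(0, 3, 6)        # unwrapped series with |dz| > Lz/2
  tru <- ion_trajectory(2, 1:3, cbind(0, 0, zu), c(5, 5, 5),
                        wrapped = FALSE)
  expect_error(detect_crossings(tru, discard = 0), "unwrap ambiguity")
})

test_that("events inside the discard window are never counted", {
  Lz <- 5
  z <- seq(0.1, 0.1 + 3 * Lz, length.out = 300) %% Lz
  tr <- ion_trajectory(1, seq_len(300) * 0.5, cbind(0, 0, z),
                       c(5, 5, Lz), wrapped = TRUE)  # 150 ns total
  ev_all <- detect_crossings(tr, discard = 0)
  ev_cut <- detect_crossings(tr, discard = 100)
  expect_identical(nrow(ev_all), 3L)
  expect_true(all(ev_cut$time > 100))
  expect_lt(nrow(ev_cut), nrow(ev_all))
})

test_that("currents follow the crossing-count arithmetic", {
  none <- data.frame(time = numeric(0), direction = numeric(0))
  expect_identical(ionic_current(none, 1, c(0, 50))$current_pA, 0)
  ev61 <- data.frame(time = seq(1, 49, length.out = 61), direction = 1)
  i61 <- ionic_current(ev61, charge = 1, window = c(0, 50))
  expect_equal(i61$current_pA, 61 * 1.602176634e-19 / 50e-9 * 1e12)
  expect_equal(round(i61$current_pA), 195)
  expect_equal(i61$error_pA, sqrt(61) / 61 * i61$current_pA)
  ev121 <- data.frame(time = seq(1, 89, length.out = 121),
                      direction = 1)
  expect_equal(ionic_current(ev121, 1, c(0, 90))$current_pA, 215.4,
               tolerance = 1e-3)
  # divalent carrier doubles the current of the same event count
  expect_equal(ionic_current(ev61, charge = 2,
                             window = c(0, 50))$current_pA,
               2 * i61$current_pA)
})

test_that("run_current books total charge exactly", {
  set.seed(62)
  Lz <- 8
  mk <- function(id, q, drift) {
    walk <- make_wrapped_walk(800, Lz, drift, 0.2)
    ion_trajectory(id, seq_len(800) * 0.05, cbind(0, 0, walk$zw),
                   c(5, 5, Lz), charge = q, wrapped = TRUE,
                   species = if (q > 0) "K" else "Cl")
  }
  trajs <- c(lapply(1:3, mk, q = 1, drift = 0.25),
             lapply(4:5, mk, q = -1, drift = -0.2))
  tab <- run_current(trajs, discard = 0, window = c(0, 40))
  tot <- tab[tab$species == "total", ]
  by_sp <- tab[tab$species != "total", ]
  expect_equal(tot$current_pA, sum(by_sp$current_pA))
  # transported charge = current x duration, species by species
  e_C <- 1.602176634e-19
  for (i in seq_len(nrow(by_sp)))
    expect_equal(by_sp$current_pA[i] * 1e-12 * 40e-9,
                 by_sp$net[i] * by_sp$charge[i] * e_C)
})

test_that("IV fits recover slope, intercept and options", {
  pts <- data.frame(voltage = c(-0.2, 0, 0.2, 0.3, 0.5))
  pts$current <- 668 * pts$voltage
  fit <- suppressWarnings(fit_iv(pts))  # exact line: summary.lm chatters
  expect_equal(fit$conductance_pS, 668)
  expect_equal(fit$se_pS, 0, tolerance = 1e-9)
  expect_equal(fit$intercept_pA, 0, tolerance = 1e-9)
  # two-point slope
  fit2 <- fit_iv(data.frame(voltage = c(0, 0.5),
                            current = c(0, 100)))
  expect_equal(fit2$conductance_pS, 200)
  # proportional fit pins the intercept
  pts$current <- pts$current + 5
  fitp <- fit_iv(pts, proportional = TRUE)
  expect_identical(fitp$intercept_pA, 0)
  # weights change the fit when errors differ (non-collinear points)
  pts$current <- pts$current + c(0, 3, -2, 1, 40)
  pts$current_error <- c(1, 1, 1, 1, 100)
  fw <- fit_iv(pts, weighted = TRUE)
  fu <- fit_iv(pts, weighted = FALSE)
  expect_false(isTRUE(all.equal(fw$conductance_pS,
                                fu$conductance_pS)))
  expect_error(fit_iv(data.frame(voltage = c(0.3, 0.3),
                                 current = c(1, 2))),
               "distinct voltages")
})

test_that("negating the field negates the current within noise", {
  kT <- thermal_energy(300)
  res <- lapply(c(-0.4, 0.4), function(V) {
    p <- sim_params(diffusion = 1, dt = 1e-3, n_steps = 2e5,
                    box_length = 14.626,
                    field = field_from_voltage(V), charge = 1,
                    seed = 63 + round(10 * V))
    trajs <- simulate_field_ensemble(p, n_ions = 12,
                                     sample_every = 10)
    tab <- run_current(trajs, discard = 10)
    tab[tab$species == "total", ]
  })
  expect_lt(abs(res[[1]]$current_pA + res[[2]]$current_pA),
            3 * sqrt(res[[1]]$error_pA^2 + res[[2]]$error_pA^2))
})
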