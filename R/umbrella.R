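#' Umbrella-sampling window record
#'
#' One biased sampling record: the harmonic bias center and spring
#' constant, the reaction-coordinate time series, optional in-plane
#' (perpendicular) samples used for the effective-area estimate, and the
#' equilibration fraction to discard.
#'
#' @param center bias center in nm.
#' @param k spring constant in kJ/mol/nm^2 (the study value is 500).
#' @param samples reaction-coordinate samples z(t) in nm.
#' @param perp_samples optional n x 2 matrix of in-plane positions in nm.
#' @param discard_fraction fraction of initial samples flagged as
#'   equilibration and excluded from analysis (default 1/6, mirroring a
#'   0.1 ns discard from 0.6 ns windows).
#' @return an object of class `umbrella_window`.
#' @export
umbrella_window <- function(center, k, samples, perp_samples = NULL,
                            discard_fraction = 1 / 6) {
  stopifnot(k > 0, is.numeric(samples), all(is.finite(samples)),
            discard_fraction >= 0, discard_fraction < 1)
  n_keep <- length(samples) - floor(length(samples) * discard_fraction)
  if (n_keep < 10)
    stop("fewer than 10 retained samples after the equilibration discard")
  if (!is.null(perp_samples)) {
    perp_samples <- as.matrix(perp_samples)
    stopifnot(ncol(perp_samples) == 2)
  }
  structure(list(center = center, k = k, samples = as.numeric(samples),
                 perp_samples = perp_samples,
                 discard_fraction = discard_fraction),
            class = "umbrella_window")
}

#' Retained (post-equilibration) samples of an umbrella window
#'
#' @param window an [umbrella_window()].
#' @return numeric vector of samples after dropping the flagged
#'   equilibration fraction.
#' @export
retained_samples <- function(window) {
  n <- length(window$samples)
  drop <- floor(n * window$discard_fraction)
  window$samples[(drop + 1):n]
}

#' @export
print.umbrella_window <- function(x, ...) {
  cat(sprintf(
    "umbrella window: center %.4g nm, k = %g kJ/mol/nm^2, %d samples (%d retained)\n",
    x$center, x$k, length(x$samples), length(retained_samples(x))))
  invisible(x)
}

#' Generate a synthetic umbrella-sampling dataset
#'
#' Lays out `n_windows` harmonic windows spaced `spacing` nm apart on a
#' known potential and samples each with the Brownian integrator, giving a
#' dataset with exact ground truth for WHAM validation.  Each window also
#' carries independent Gaussian in-plane samples with standard deviations
#' `perp_spread`, consumed by the effective-area estimate.
#'
#' Defaults mirror the study layout: 209 windows at 0.07 nm spacing with
#' k = 500 kJ/mol/nm^2 span a 14.626 nm periodic box (the centers wrap
#' onto the box within one spacing).  The first 1/6 of each window's
#' samples is flagged as equilibration.
#'
#' @param potential ground-truth [potential_1d()].
#' @param n_windows number of windows.
#' @param spacing window spacing in nm.
#' @param k spring constant in kJ/mol/nm^2.
#' @param params a [sim_params()]; `n_steps` samples are recorded per
#'   window.
#' @param perp_spread in-plane standard deviations `c(xi1, xi2)` in nm
#'   (default 1.2/1.2 nm, a monovalent-cation-like bulk spread).
#' @param discard_fraction equilibration fraction per window.
#' @param start_center center of the first window in nm.
#' @param check_overlap warn when adjacent window histograms do not
#'   overlap.
#' @return a list of [umbrella_window()] objects, class `umbrella_set`.
#' @export
generate_umbrella_dataset <- function(potential, n_windows = 209,
                                      spacing = 0.07, k = 500, params,
                                      perp_spread = c(1.2, 1.2),
                                      discard_fraction = 1 / 6,
                                      start_center = 0,
                                      check_overlap = TRUE) {
  stopifnot(n_windows >= 1, spacing > 0, k > 0,
            length(perp_spread) == 2, all(perp_spread > 0))
  L <- potential$periodic_length
  if (!is.null(L)) {
    if (n_windows * spacing > L + spacing)
      stop("windows overrun the periodic length by more than one spacing: ",
           n_windows, " x ", spacing, " nm > ", L, " nm")
  }
  centers <- start_center + (seq_len(n_windows) - 1) * spacing
  if (!is.null(L)) centers <- centers %% L

  if (!is.null(params$seed)) set.seed(params$seed)
  p2 <- params; p2$seed <- NULL
  run <- .bd_run(potential, p2, bias_centers = centers, bias_k = k)
  windows <- lapply(seq_len(n_windows), function(i) {
    perp <- cbind(rnorm(params$n_steps, sd = perp_spread[1]),
                  rnorm(params$n_steps, sd = perp_spread[2]))
    umbrella_window(center = centers[i], k = k, samples = run$z[, i],
                    perp_samples = perp,
                    discard_fraction = discard_fraction)
  })
  out <- structure(windows, class = c("umbrella_set", "list"),
                   periodic_length = L)
  if (check_overlap && n_windows > 1) .warn_window_gaps(out)
  out
}

#' @export
print.umbrella_set <- function(x, ...) {
  L <- attr(x, "periodic_length")
  cat(sprintf("umbrella dataset: %d windows%s\n", length(x),
              if (!is.null(L)) sprintf(", periodic L = %g nm", L) else ""))
  invisible(x)
}

# Warn when adjacent (by center order) window histograms share no bin.
.warn_window_gaps <- function(windows) {
  L <- attr(windows, "periodic_length")
  centers <- vapply(windows, `[[`, numeric(1), "center")
  ord <- order(centers)
  samp <- lapply(windows[ord], retained_samples)
  rng <- range(unlist(samp))
  breaks <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = 512)
  occ <- lapply(samp, function(s)
    unique(findInterval(s, breaks)))
  pairs <- cbind(seq_along(occ)[-length(occ)], seq_along(occ)[-1])
  if (!is.null(L)) pairs <- rbind(pairs, c(length(occ), 1))
  bad <- pairs[!apply(pairs, 1, function(p)
    length(intersect(occ[[p[1]]], occ[[p[2]]])) > 0), , drop = FALSE]
  if (nrow(bad) > 0)
    warning("non-overlapping neighbor histograms between windows centered ",
            "at ", paste(sprintf("%.3g/%.3g nm",
                                 centers[ord][bad[, 1]],
                                 centers[ord][bad[, 2]]),
                         collapse = ", "))
  invisible(NULL)
}
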