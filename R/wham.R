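# Weighted histogram analysis method (WHAM) for 1-D umbrella-sampling
# data, with a cyclic (periodic reaction coordinate) variant and
# window-level bootstrap errors.

#' Binned free-energy profile
#'
#' Constructor for the PMF container returned by [solve_wham()].  The
#' reference convention is recorded: `"min_zero"` (minimum shifted to
#' zero, for display) or `"bulk_zero"` (mean over a declared unbound/bulk
#' interval shifted to zero, required for binding analyses).
#'
#' @param bin_centers bin centers in nm.
#' @param W free energy per bin in kJ/mol (`NA` for unoccupied bins).
#' @param errors per-bin error estimates in kJ/mol (`NA` when not yet
#'   computed).
#' @param periodic_length periodic length in nm or `NULL`.
#' @param reference `"min_zero"` or `"bulk_zero"`.
#' @param bulk_interval `c(lo, hi)` in nm for `"bulk_zero"`; `lo > hi`
#'   denotes an interval wrapping around the periodic seam.
#' @param temperature temperature in K.
#' @param details list of solver diagnostics.
#' @return an object of class `pmf_profile`.
#' @export
pmf_profile <- function(bin_centers, W, errors = rep(NA_real_,
                          length(W)),
                        periodic_length = NULL,
                        reference = c("min_zero", "bulk_zero"),
                        bulk_interval = NULL, temperature = 300,
                        details = list()) {
  reference <- match.arg(reference)
  stopifnot(length(W) == length(bin_centers),
            length(errors) == length(bin_centers))
  if (reference == "bulk_zero") {
    stopifnot(!is.null(bulk_interval))
    m <- mean(W[.in_interval(bin_centers, bulk_interval)], na.rm = TRUE)
    if (!is.finite(m) || abs(m) > 1e-9)
      stop("bulk_zero profile must average to 0 over the bulk interval")
  }
  structure(list(bin_centers = as.numeric(bin_centers),
                 W = as.numeric(W), errors = as.numeric(errors),
                 periodic_length = periodic_length,
                 reference = reference, bulk_interval = bulk_interval,
                 temperature = temperature,
                 kT = thermal_energy(temperature), details = details),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  occ <- is.finite(x$W)
  cat(sprintf("PMF profile: %d bins (%d occupied), reference %s%s\n",
              length(x$W), sum(occ), x$reference,
              if (!is.null(x$periodic_length))
                sprintf(", cyclic L = %g nm", x$periodic_length) else ""))
  cat(sprintf("  range [%.3g, %.3g] kJ/mol", min(x$W[occ]), max(x$W[occ])))
  if (any(is.finite(x$errors)))
    cat(sprintf(", mean error %.3g kJ/mol",
                mean(x$errors[is.finite(x$errors)])))
  cat("\n")
  if (!is.null(x$details$iterations))
    cat(sprintf("  WHAM: %d iterations, residual %.2g kJ/mol\n",
                x$details$iterations, x$details$residual))
  invisible(x)
}

#' @export
plot.pmf_profile <- function(x, ...) {
  graphics::plot(x$bin_centers, x$W, type = "l",
                 xlab = "z (nm)", ylab = "W(z) (kJ/mol)", ...)
  if (any(is.finite(x$errors))) {
    ok <- is.finite(x$errors) & is.finite(x$W)
    graphics::arrows(x$bin_centers[ok], x$W[ok] - x$errors[ok],
                     x$bin_centers[ok], x$W[ok] + x$errors[ok],
                     length = 0.02, angle = 90, code = 3,
                     col = "grey60")
  }
  invisible(x)
}

# TRUE for centers inside interval c(lo, hi); lo > hi wraps (periodic).
.in_interval <- function(z, interval) {
  if (interval[1] <= interval[2])
    z >= interval[1] & z <= interval[2]
  else
    z >= interval[1] | z <= interval[2]
}

# Shared binning/bias setup for solve_wham and bootstrap_pmf.
.wham_setup <- function(windows, n_bins, temperature, periodic_length) {
  kT <- thermal_energy(temperature)
  samp <- lapply(windows, retained_samples)
  if (is.null(periodic_length)) {
    rng <- range(unlist(samp))
    breaks <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = n_bins + 1)
  } else {
    samp <- lapply(samp, function(s) s %% periodic_length)
    breaks <- seq(0, periodic_length, length.out = n_bins + 1)
  }
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  counts <- t(vapply(samp, function(s) {
    idx <- findInterval(s, breaks, rightmost.closed = TRUE)
    tabulate(idx, nbins = n_bins)
  }, numeric(n_bins)))
  cmat <- t(vapply(windows, function(w) {
    d <- centers - w$center
    if (!is.null(periodic_length))
      d <- d - periodic_length * round(d / periodic_length)
    exp(-0.5 * w$k * d^2 / kT)
  }, numeric(n_bins)))
  list(kT = kT, breaks = breaks, centers = centers, counts = counts,
       cmat = cmat, N = rowSums(counts),
       periodic = !is.null(periodic_length))
}

.wham_core <- function(setup, counts, N, tol, max_iter, f_init = NULL) {
  if (is.null(f_init)) f_init <- rep(1, length(N))
  sol <- wham_solve_cpp(counts = counts, N_i = N, cmat = setup$cmat,
                        f_init = f_init, kT = setup$kT, tol = tol,
                        max_iter = as.integer(max_iter))
  if (!sol$converged)
    stop(sprintf(
      "WHAM did not converge in %d iterations (residual %.3g kJ/mol)",
      sol$iterations, sol$residual))
  W <- -setup$kT * log(sol$p)
  W[sol$p <= 0] <- NA_real_
  list(W = W, sol = sol)
}

# A gap is an empty bin *between* occupied regions: on a line, any empty
# bin inside the occupied range; on a circle, more than one empty run
# (a single contiguous uncovered arc just bounds the sampled support).
.check_gaps <- function(setup, counts) {
  tot <- colSums(counts)
  if (all(tot > 0)) return(invisible(NULL))
  occ <- which(tot > 0)
  if (length(occ) == 0)
    stop("histogram gap: no samples in any bin")
  gap_bins <- if (!setup$periodic) {
    setdiff(seq(min(occ), max(occ)), occ)
  } else {
    emp <- tot == 0
    runs <- rle(emp)
    n_runs <- sum(runs$values)
    if (emp[1] && emp[length(emp)]) n_runs <- n_runs - 1
    if (n_runs <= 1) integer(0) else which(emp)
  }
  if (length(gap_bins) == 0) return(invisible(NULL))
  stop("histogram gap: no samples in bins centered at ",
       paste(signif(setup$centers[utils::head(gap_bins, 8)], 4),
             collapse = ", "),
       if (length(gap_bins) > 8) sprintf(" (and %d more)",
                                         length(gap_bins) - 8) else "",
       " nm; windows do not cover the binned range")
}

.apply_reference <- function(W, centers, reference, bulk_interval) {
  if (reference == "min_zero") {
    W - min(W, na.rm = TRUE)
  } else {
    sel <- .in_interval(centers, bulk_interval)
    if (!any(sel & is.finite(W)))
      stop("no occupied bins inside the bulk interval")
    W - mean(W[sel], na.rm = TRUE)
  }
}

#' Reconstruct a PMF from umbrella windows by WHAM
#'
#' Self-consistent WHAM iteration: unbiased probability
#' `p(b) = sum_i n_i(b) / sum_i N_i f_i exp(-beta w_i(b))` with
#' `f_i^-1 = sum_b p(b) exp(-beta w_i(b))`, iterated until the maximum
#' change of `kT ln f_i` drops below `tol`.  The bias is
#' `w_i(b) = k_i/2 * d(z_b, c_i)^2` with `d` the minimum-image distance on
#' a periodic (cyclic) coordinate and the plain difference otherwise.  The
#' profile is `W = -kT ln p`, shifted per the reference convention.
#'
#' @inheritParams pmf_profile
#' @param windows list of [umbrella_window()] (an `umbrella_set`).
#' @param n_bins number of bins (default 200, about the window
#'   resolution of the study layout).
#' @param temperature temperature in K.
#' @param periodic_length periodic length in nm for a cyclic PMF, or
#'   `NULL`.
#' @param tol convergence tolerance on `max |d(kT ln f_i)|` in kJ/mol.
#' @param max_iter iteration cap.
#' @return a [pmf_profile()]; `details` carries the iteration count and
#'   final residual.
#' @examples
#' \donttest{
#' pot <- periodic_wells_potential(10, n_wells = 2, length = 5)
#' ws <- generate_umbrella_dataset(pot, n_windows = 51, spacing = 5 / 51,
#'   k = 500, params = sim_params(n_steps = 3000, dt = 2e-4, seed = 1))
#' pmf <- solve_wham(ws, n_bins = 100, periodic_length = 5)
#' }
#' @export
solve_wham <- function(windows, n_bins = 200, temperature = 300,
                       periodic_length = attr(windows, "periodic_length"),
                       tol = 1e-6, max_iter = 1e5,
                       reference = c("min_zero", "bulk_zero"),
                       bulk_interval = NULL) {
  reference <- match.arg(reference)
  stopifnot(length(windows) >= 1, tol > 0)
  setup <- .wham_setup(windows, n_bins, temperature, periodic_length)
  .check_gaps(setup, setup$counts)
  res <- .wham_core(setup, setup$counts, setup$N, tol, max_iter)
  W <- .apply_reference(res$W, setup$centers, reference, bulk_interval)
  pmf_profile(setup$centers, W, periodic_length = periodic_length,
              reference = reference, bulk_interval = bulk_interval,
              temperature = temperature,
              details = list(iterations = res$sol$iterations,
                             residual = res$sol$residual,
                             p = res$sol$p, f = res$sol$f,
                             n_bins = n_bins, tol = tol))
}

#' Bootstrap error estimates for a WHAM profile
#'
#' Re-solves WHAM on `n_boot` resampled datasets and attaches the per-bin
#' standard deviation over replicas (after alignment to the common
#' reference) as the error estimate.  The default resampling unit is the
#' complete window (window-level bootstrap), appropriate when
#' within-window samples are autocorrelated; `unit = "blocks"` switches to
#' a within-window moving-block bootstrap.
#'
#' A replica whose WHAM solve fails (gap or non-convergence) is retried
#' once with fresh resampling, then counted as failed; more than 10%
#' failures aborts.
#'
#' @inheritParams solve_wham
#' @param n_boot number of bootstrap replicas (default 200, the study
#'   setting).
#' @param seed integer seed for reproducible resampling, or `NULL`.
#' @param unit `"window"` or `"blocks"`.
#' @return the base [pmf_profile()] with `errors` filled; `details` gains
#'   `n_boot` and `n_failed`.
#' @export
bootstrap_pmf <- function(windows, n_bins = 200, temperature = 300,
                          periodic_length = attr(windows,
                                                 "periodic_length"),
                          tol = 1e-6, max_iter = 1e5,
                          reference = c("min_zero", "bulk_zero"),
                          bulk_interval = NULL, n_boot = 200,
                          seed = NULL, unit = c("window", "blocks")) {
  reference <- match.arg(reference)
  unit <- match.arg(unit)
  stopifnot(n_boot >= 2)
  base <- solve_wham(windows, n_bins, temperature, periodic_length,
                     tol, max_iter, reference, bulk_interval)
  setup <- .wham_setup(windows, n_bins, temperature, periodic_length)
  f0 <- base$details$f
  nw <- length(windows)
  if (!is.null(seed)) set.seed(seed)

  one_replica <- function() {
    if (unit == "window") {
      idx <- sample.int(nw, nw, replace = TRUE)
      counts <- setup$counts[idx, , drop = FALSE]
      N <- setup$N[idx]
      cm <- setup$cmat[idx, , drop = FALSE]
      fi <- f0[idx]
      su <- setup; su$cmat <- cm
    } else {
      samp <- lapply(windows, function(w) {
        s <- retained_samples(w)
        b <- max(1L, as.integer(ceiling(length(s)^(2 / 3))))
        starts <- sample.int(length(s) - b + 1L,
                             ceiling(length(s) / b), replace = TRUE)
        unlist(lapply(starts, function(j) s[j:(j + b - 1L)]))[
          seq_along(s)]
      })
      if (!is.null(periodic_length))
        samp <- lapply(samp, function(s) s %% periodic_length)
      counts <- t(vapply(samp, function(s) {
        idx <- findInterval(s, setup$breaks, rightmost.closed = TRUE)
        idx[idx < 1] <- 1L
        idx[idx > length(setup$centers)] <- length(setup$centers)
        tabulate(idx, nbins = length(setup$centers))
      }, numeric(length(setup$centers))))
      N <- rowSums(counts)
      fi <- f0
      su <- setup
    }
    .check_gaps(su, counts)
    res <- .wham_core(su, counts, N, tol, max_iter, f_init = fi)
    res$W
  }

  Wmat <- matrix(NA_real_, nrow = n_boot, ncol = length(setup$centers))
  n_failed <- 0L
  for (r in seq_len(n_boot)) {
    Wr <- tryCatch(one_replica(), error = function(e)
      tryCatch(one_replica(), error = function(e2) NULL))
    if (is.null(Wr)) { n_failed <- n_failed + 1L; next }
    Wr <- if (reference == "bulk_zero") {
      .apply_reference(Wr, setup$centers, reference, bulk_interval)
    } else {
      # align to the base profile over jointly occupied bins so replica
      # spread reflects shape variability, not the arbitrary gauge
      common <- is.finite(Wr) & is.finite(base$W)
      Wr - mean(Wr[common] - base$W[common])
    }
    Wmat[r, ] <- Wr
  }
  if (n_failed > 0.1 * n_boot)
    stop(n_failed, " of ", n_boot, " bootstrap replicas failed")

  n_occ <- colSums(is.finite(Wmat))
  errors <- apply(Wmat, 2, sd, na.rm = TRUE)
  errors[n_occ < n_boot / 2] <- NA_real_
  base$errors <- errors
  base$details$n_boot <- n_boot
  base$details$n_failed <- n_failed
  base
}

#' Signed PMF extremum (deepest well or highest barrier)
#'
#' On a bulk-referenced profile, returns the deepest well (most negative
#' `W`) when any well exists, otherwise the highest barrier (most positive
#' `W`); the sign convention of a two-column free-energy table where a
#' minus sign denotes a well and a plus sign a barrier.  Exact ties are
#' broken toward the smallest `|z|`.
#'
#' @param profile a bulk-referenced [pmf_profile()].
#' @param search_interval optional `c(lo, hi)` in nm restricting the
#'   search.
#' @return list with `z` (nm), `value` (kJ/mol, signed), `kind`
#'   (`"well"` or `"barrier"`) and `error` (kJ/mol or `NA`).
#' @export
pmf_extremum <- function(profile, search_interval = NULL) {
  stopifnot(inherits(profile, "pmf_profile"))
  if (profile$reference != "bulk_zero")
    stop("pmf_extremum requires a bulk_zero-referenced profile")
  sel <- is.finite(profile$W)
  if (!is.null(search_interval))
    sel <- sel & .in_interval(profile$bin_centers, search_interval)
  if (!any(sel)) stop("empty search interval")
  z <- profile$bin_centers[sel]
  W <- profile$W[sel]
  err <- profile$errors[sel]
  if (any(W < 0)) {
    target <- min(W); kind <- "well"
  } else {
    target <- max(W); kind <- "barrier"
  }
  hits <- which(W == target)
  best <- hits[which.min(abs(z[hits]))]
  list(z = z[best], value = target, kind = kind, error = err[best])
}
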