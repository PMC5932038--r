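# Standard free energy of binding from a 1-D PMF, with the
# effective-sampled-area correction that converts the 1-D Boltzmann
# integral into a volume (no restraints perpendicular to the reaction
# coordinate).

#' Effective sampled area from in-plane covariance eigenvalues
#'
#' The in-plane positions of the ion in bulk-phase windows are treated as
#' Gaussian; the effective area perpendicular to the reaction coordinate
#' is `A = 2*pi*xi1*xi2`, where `xi1^2` and `xi2^2` are the eigenvalues of
#' the 2x2 sample covariance matrix of the pooled `(x1, x2)` samples.
#' Using eigenvalues (not marginal variances) makes the estimate invariant
#' under rotation of the in-plane frame.
#'
#' @param perp_samples n x 2 matrix of in-plane positions (nm), pooled
#'   over bulk windows, or a list of such matrices (e.g. from several
#'   windows).
#' @param method `"pooled"` (default) pools all samples before the
#'   covariance; `"per_window"` averages the per-matrix areas.
#' @return list with `area` (nm^2), `eigenvalues` (`xi1^2`, `xi2^2`,
#'   nm^2) and `n` (sample count).
#' @examples
#' set.seed(1)
#' effective_area(matrix(rnorm(2e4), ncol = 2))$area  # ~ 2*pi
#' @export
effective_area <- function(perp_samples, method = c("pooled",
                                                    "per_window")) {
  method <- match.arg(method)
  if (is.list(perp_samples) && !is.matrix(perp_samples)) {
    if (method == "per_window") {
      parts <- lapply(perp_samples, effective_area)
      return(list(area = mean(vapply(parts, `[[`, numeric(1), "area")),
                  eigenvalues = rowMeans(vapply(parts, `[[`,
                                                numeric(2),
                                                "eigenvalues")),
                  n = sum(vapply(parts, `[[`, numeric(1), "n"))))
    }
    perp_samples <- do.call(rbind, perp_samples)
  }
  perp_samples <- as.matrix(perp_samples)
  stopifnot(ncol(perp_samples) == 2)
  if (nrow(perp_samples) < 10)
    stop("need at least 10 pooled in-plane samples")
  ev <- eigen(cov(perp_samples), symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev, 1e-300))
    stop("degenerate in-plane covariance (zero eigenvalue)")
  list(area = 2 * pi * sqrt(ev[1]) * sqrt(ev[2]),
       eigenvalues = ev, n = nrow(perp_samples))
}

#' Pool in-plane samples from bulk-phase windows
#'
#' @param windows an `umbrella_set` or list of [umbrella_window()].
#' @param bulk_interval `c(lo, hi)` in nm; windows whose centers fall
#'   *outside* this (bound) interval are treated as bulk phase.
#' @return n x 2 matrix of pooled in-plane samples.
#' @export
bulk_perp_samples <- function(windows, bulk_interval) {
  centers <- vapply(windows, `[[`, numeric(1), "center")
  sel <- !.in_interval(centers, bulk_interval)
  if (!any(sel)) stop("no windows outside the bound interval")
  mats <- lapply(windows[sel], function(w) {
    if (is.null(w$perp_samples)) return(NULL)
    n <- nrow(w$perp_samples)
    drop <- floor(n * w$discard_fraction)
    w$perp_samples[(drop + 1):n, , drop = FALSE]
  })
  mats <- mats[!vapply(mats, is.null, logical(1))]
  if (length(mats) == 0) stop("bulk windows carry no in-plane samples")
  do.call(rbind, mats)
}

#' Standard free energy of binding from a bulk-referenced PMF
#'
#' `dG0 = -kT * ln( C0 * A * I )` with `I = integral over the bound
#' interval of exp(-W(z)/kT) dz` by trapezoidal quadrature on the PMF
#' grid, `A` the effective sampled area and `C0` the standard
#' concentration (one molecule per 1.6606 nm^3 = 1 mol/L).  `W` must be
#' referenced to zero in the bulk (unbound) region.  When the profile
#' carries bootstrap errors, the error on `dG0` is propagated by
#' per-bin Gaussian resampling of `W`.
#'
#' @param pmf a `bulk_zero`-referenced [pmf_profile()].
#' @param bound_interval `c(lo, hi)` in nm; the study preset is
#'   `c(-6.0, 7.5)`.
#' @param area effective sampled area in nm^2 (see [effective_area()];
#'   study presets per ion: Ba 3.09, Ca 3.04, Mg 5.15, K 9.09, Na
#'   3.30).
#' @param temperature temperature in K (defaults to the profile's).
#' @param n_resample Monte-Carlo draws for error propagation.
#' @return an object of class `binding_result`: `dG0` and `dG0_error`
#'   (kJ/mol), `area` (nm^2), `eigenvalues` (nm^2 or `NULL`),
#'   `boltzmann_integral` (nm), `bound_interval`.
#' @export
standard_binding_free_energy <- function(pmf, bound_interval, area,
                                         temperature = NULL,
                                         n_resample = 200) {
  stopifnot(inherits(pmf, "pmf_profile"), length(bound_interval) == 2,
            bound_interval[1] < bound_interval[2], area > 0)
  if (pmf$reference != "bulk_zero")
    stop("PMF must be bulk_zero-referenced for binding analysis")
  if (is.null(temperature)) temperature <- pmf$temperature
  kT <- thermal_energy(temperature)

  eigenvalues <- attr(area, "eigenvalues")
  if (is.list(area)) { eigenvalues <- area$eigenvalues; area <- area$area }

  z <- pmf$bin_centers
  W <- pmf$W
  support <- range(z[is.finite(W)])
  if (bound_interval[1] < support[1] - diff(support) / length(z) ||
      bound_interval[2] > support[2] + diff(support) / length(z))
    stop("bound interval exceeds the PMF support [",
         signif(support[1], 4), ", ", signif(support[2], 4), "] nm")

  integral_of <- function(Wv) {
    inside <- z > bound_interval[1] & z < bound_interval[2]
    if (any(inside & !is.finite(Wv)))
      stop("unoccupied bins inside the bound interval")
    xs <- c(bound_interval[1], z[inside], bound_interval[2])
    ys <- approx(z[is.finite(Wv)], Wv[is.finite(Wv)], xout = xs,
                 rule = 2)$y
    f <- exp(-ys / kT)
    sum(diff(xs) * (f[-1] + f[-length(f)]) / 2)
  }

  I <- integral_of(W)
  dG0 <- -kT * log(area * I / .std_volume_nm3)

  dG0_error <- NA_real_
  if (any(is.finite(pmf$errors))) {
    err <- ifelse(is.finite(pmf$errors), pmf$errors, 0)
    draws <- vapply(seq_len(n_resample), function(i) {
      Wi <- W + rnorm(length(W), sd = err)
      -kT * log(area * integral_of(Wi) / .std_volume_nm3)
    }, numeric(1))
    dG0_error <- sd(draws)
  }

  structure(list(dG0 = dG0, dG0_error = dG0_error, area = area,
                 eigenvalues = eigenvalues, boltzmann_integral = I,
                 bound_interval = bound_interval,
                 temperature = temperature),
            class = "binding_result")
}

#' @export
print.binding_result <- function(x, ...) {
  cat(sprintf("standard free energy of binding: dG0 = %.2f%s kJ/mol\n",
              x$dG0,
              if (is.finite(x$dG0_error))
                sprintf(" +/- %.2f", x$dG0_error) else ""))
  cat(sprintf(
    "  effective area A = %.3g nm^2, Boltzmann integral = %.4g nm,\n",
    x$area, x$boltzmann_integral))
  cat(sprintf("  bound interval [%g, %g] nm, T = %g K\n",
              x$bound_interval[1], x$bound_interval[2], x$temperature))
  invisible(x)
}
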