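# Applied-voltage permeation analysis: periodic-boundary crossing counts,
# ionic currents and the current-voltage fit.

#' Transmembrane voltage from a constant field
#'
#' In a periodic single-membrane box a constant axial field `E` (V/nm)
#' corresponds to the voltage `V = E * L_z` with `L_z` the axial box
#' dimension (14.626 nm in the study; `E` chosen there to give -0.2 to
#' 1.0 V).
#'
#' @param field E in V/nm.
#' @param box_length L_z in nm.
#' @return voltage in V.
#' @examples
#' voltage_from_field(0.3 / 14.626, 14.626)
#' @export
voltage_from_field <- function(field, box_length = 14.626) {
  stopifnot(box_length > 0)
  field * box_length
}

#' @rdname voltage_from_field
#' @param voltage V in volt.
#' @return `field_from_voltage`: field in V/nm.
#' @export
field_from_voltage <- function(voltage, box_length = 14.626) {
  stopifnot(box_length > 0)
  voltage / box_length
}

#' Detect signed periodic-boundary crossings
#'
#' Unwraps the axial coordinate by minimum image per frame pair and
#' records a signed event each time the unwrapped coordinate passes a
#' periodic image of `boundary_z` (+1 forward, -1 backward).  Events
#' before `discard` ns are dropped (default 10 ns, the study's excluded
#' initial stretch).  Frame spacing must keep `|dz| < L_z/2` between
#' frames; larger jumps make the unwrap ambiguous and raise an error.
#'
#' @param traj an [ion_trajectory()].
#' @param boundary_z boundary plane position in nm (default 0, the box
#'   face).
#' @param discard initial time to exclude in ns.
#' @return data.frame with columns `time` (ns), `direction` (+1/-1) and
#'   `ion_id`; attribute `analysis_window`.
#' @export
detect_crossings <- function(traj, boundary_z = 0, discard = 10) {
  stopifnot(inherits(traj, "ion_trajectory"))
  Lz <- traj$box[3]
  z <- traj$positions[, 3]
  dz <- diff(z)
  dzm <- dz - Lz * round(dz / Lz)
  if (traj$wrapped) {
    # minimum-image jumps are bounded by Lz/2 by construction; jumps
    # close to that bound are the observable signature of frames too
    # coarse to unwrap unambiguously
    if (any(abs(dzm) >= 0.45 * Lz))
      stop("unwrap ambiguity: |dz| approaches Lz/2 between frames of ",
           "ion ", traj$ion_id, "; frame spacing too coarse")
    zu <- c(z[1], z[1] + cumsum(dzm))
  } else {
    if (any(abs(dz) >= Lz / 2))
      stop("unwrap ambiguity: |dz| >= Lz/2 between frames of ion ",
           traj$ion_id, "; frame spacing too coarse")
    zu <- z
  }
  g <- floor((zu - boundary_z) / Lz)
  dg <- diff(g)
  idx <- which(dg != 0)
  ev <- data.frame(time = traj$times[idx + 1],
                   direction = sign(dg[idx]),
                   ion_id = rep(traj$ion_id, length(idx)))
  ev <- ev[ev$time > discard, , drop = FALSE]
  attr(ev, "analysis_window") <- c(max(discard, traj$times[1]),
                                   traj$times[length(traj$times)])
  ev
}

#' Ionic current from crossing events
#'
#' `I = (net signed crossings) * q * e / duration`, reported in pA, with
#' a counting error of `sqrt(N_forward + N_backward)` crossings
#' (independent-event approximation).
#'
#' @param events data.frame of crossing events (see
#'   [detect_crossings()]), possibly concatenated over ions.
#' @param charge ion charge q in elementary charges.
#' @param window analysis window `c(t_start, t_end)` in ns (defaults to
#'   the events' recorded window).
#' @return list with `current_pA`, `error_pA`, `net`, `n_forward`,
#'   `n_backward`, `window`.
#' @examples
#' ev <- data.frame(time = seq(1, 50, length.out = 61), direction = 1)
#' ionic_current(ev, charge = 1, window = c(0, 50))$current_pA  # ~195
#' @export
ionic_current <- function(events, charge = 1, window = NULL) {
  if (is.null(window)) window <- attr(events, "analysis_window")
  stopifnot(!is.null(window), length(window) == 2,
            window[2] > window[1])
  nf <- sum(events$direction > 0)
  nb <- sum(events$direction < 0)
  dur_s <- (window[2] - window[1]) * 1e-9
  fac <- charge * .e_C / dur_s * 1e12   # pA per net crossing
  list(current_pA = (nf - nb) * fac, error_pA = sqrt(nf + nb) * fac,
       net = nf - nb, n_forward = nf, n_backward = nb, window = window)
}

#' Current of a permeation run (per species and total)
#'
#' Detects crossings in every trajectory of a run and aggregates net
#' counts into currents per species (trajectories sharing a
#' species/charge) and in total.
#'
#' @param trajectories list of [ion_trajectory()].
#' @inheritParams detect_crossings
#' @param window analysis window `c(t_start, t_end)` in ns; defaults to
#'   `discard` up to the last frame.
#' @return data.frame with one row per species plus a `"total"` row:
#'   `species`, `charge`, `net`, `current_pA`, `error_pA`.
#' @export
run_current <- function(trajectories, boundary_z = 0, discard = 10,
                        window = NULL) {
  stopifnot(length(trajectories) >= 1)
  if (is.null(window))
    window <- c(discard,
                max(vapply(trajectories, function(tr)
                  tr$times[length(tr$times)], numeric(1))))
  key <- vapply(trajectories, function(tr)
    if (!is.null(tr$species)) tr$species
    else sprintf("q%+g", tr$charge), character(1))
  charges <- vapply(trajectories, `[[`, numeric(1), "charge")
  rows <- lapply(unique(key), function(kk) {
    sel <- which(key == kk)
    evs <- do.call(rbind, lapply(trajectories[sel], detect_crossings,
                                 boundary_z = boundary_z,
                                 discard = discard))
    cur <- ionic_current(evs, charge = charges[sel[1]], window = window)
    data.frame(species = kk, charge = charges[sel[1]], net = cur$net,
               current_pA = cur$current_pA, error_pA = cur$error_pA)
  })
  out <- do.call(rbind, rows)
  total <- data.frame(species = "total", charge = NA_real_,
                      net = sum(out$net),
                      current_pA = sum(out$current_pA),
                      error_pA = sqrt(sum(out$error_pA^2)))
  res <- rbind(out, total)
  attr(res, "analysis_window") <- window
  res
}

#' Fit the current-voltage relation
#'
#' Ordinary (or error-weighted) least squares of `I = g*V + I0`; the
#' slope is the conductance in pS (pA/V).  With `proportional = TRUE`
#' the intercept is fixed at zero.
#'
#' @param points data.frame with columns `voltage` (V), `current` (pA)
#'   and optionally `current_error` (pA; used as weights when present
#'   and `weighted = TRUE`).
#' @param weighted use `1/error^2` weights when errors are available.
#' @param proportional force the fit through the origin.
#' @return an object of class `iv_fit`: `conductance_pS`, `se_pS`,
#'   `intercept_pA`, `r_squared` and the underlying `lm` fit.
#' @examples
#' fit_iv(data.frame(voltage = c(0, 0.5), current = c(0, 100)))
#' @export
fit_iv <- function(points, weighted = TRUE, proportional = FALSE) {
  stopifnot(all(c("voltage", "current") %in% names(points)))
  if (length(unique(points$voltage)) < 2)
    stop("need at least 2 distinct voltages to fit an IV relation")
  w <- NULL
  if (weighted && "current_error" %in% names(points) &&
      all(is.finite(points$current_error)) &&
      all(points$current_error > 0))
    w <- 1 / points$current_error^2
  fml <- if (proportional) current ~ voltage + 0 else current ~ voltage
  fit <- lm(fml, data = points, weights = w)
  cf <- summary(fit)$coefficients
  g <- cf["voltage", "Estimate"]
  se <- cf["voltage", "Std. Error"]
  i0 <- if (proportional) 0 else cf["(Intercept)", "Estimate"]
  ssr <- sum((points$current - stats::fitted(fit))^2)
  sst <- sum((points$current - mean(points$current))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else NA_real_
  structure(list(conductance_pS = g, se_pS = se, intercept_pA = i0,
                 r_squared = r2, fit = fit),
            class = "iv_fit")
}

#' @export
print.iv_fit <- function(x, ...) {
  cat(sprintf(
    "IV fit: conductance g = (%.4g +/- %.2g) pS, intercept %.3g pA, R^2 = %.4f\n",
    x$conductance_pS, x$se_pS, x$intercept_pA, x$r_squared))
  invisible(x)
}
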