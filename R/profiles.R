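# Static-geometry profiles along the pore axis: hydration-shell counts
# per ion position and a simplified largest-inscribed-sphere pore radius.

#' Hydration-shell definition
#'
#' Nested radial cutoffs for the first and second hydration shells of an
#' ion species.  Defaults (overridable) follow standard ion-oxygen
#' radial-distribution-function minima: Mg 0.28/0.50, Ca 0.32/0.55, Ba
#' 0.35/0.58, Na 0.32/0.56, K 0.36/0.60, Cl 0.39/0.62 nm.
#'
#' @param species species tag (e.g. `"K"`); known tags fill default
#'   radii.
#' @param first_shell_radius first-shell cutoff in nm.
#' @param second_shell_radius second-shell cutoff in nm.
#' @return an object of class `shell_definition`.
#' @examples
#' shell_definition("K")
#' @export
shell_definition <- function(species,
                             first_shell_radius = NULL,
                             second_shell_radius = NULL) {
  defaults <- list(Mg = c(0.28, 0.50), Ca = c(0.32, 0.55),
                   Ba = c(0.35, 0.58), Na = c(0.32, 0.56),
                   K = c(0.36, 0.60), Cl = c(0.39, 0.62))
  if (is.null(first_shell_radius) || is.null(second_shell_radius)) {
    if (!species %in% names(defaults))
      stop("no default shell radii for species '", species,
           "'; supply first_shell_radius and second_shell_radius")
    first_shell_radius <- defaults[[species]][1]
    second_shell_radius <- defaults[[species]][2]
  }
  if (!(first_shell_radius > 0 &&
        second_shell_radius > first_shell_radius))
    stop("shell radii must satisfy 0 < first < second")
  structure(list(species = species,
                 first_shell_radius = first_shell_radius,
                 second_shell_radius = second_shell_radius),
            class = "shell_definition")
}

# squared minimum-image distances from one point to a point set
.dist2_pbc <- function(point, pts, box = NULL) {
  d <- sweep(pts, 2, point)
  if (!is.null(box))
    for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  rowSums(d^2)
}

#' Hydration numbers along the pore axis
#'
#' Per frame, counts solvent points within the first shell (`n1`) and in
#' the annulus between the first and second shells (`n2`) of the ion,
#' using minimum-image distances when a periodic box is given; counts
#' are binned by the ion's axial position and averaged.
#'
#' @param ion_positions n_frames x 3 matrix of ion positions (nm), or an
#'   [ion_trajectory()].
#' @param solvent list of n_frames point matrices (or one matrix reused
#'   for all frames).
#' @param shells a [shell_definition()].
#' @param box periodic box `c(Lx, Ly, Lz)` in nm, or `NULL`.
#' @param z_breaks bin edges for the axial coordinate (default: 0.1 nm
#'   bins spanning the data).
#' @return data.frame of class `hydration_profile` with `z`, `n1`, `n2`
#'   (mean counts) and `n_frames` per bin; per-frame counts in attribute
#'   `frames`.
#' @export
hydration_numbers <- function(ion_positions, solvent, shells,
                              box = NULL, z_breaks = NULL) {
  if (inherits(ion_positions, "ion_trajectory")) {
    if (is.null(box)) box <- ion_positions$box
    ion_positions <- ion_positions$positions
  }
  ion_positions <- as.matrix(ion_positions)
  stopifnot(ncol(ion_positions) == 3)
  if (!inherits(shells, "shell_definition"))
    stop("missing shell definition: supply a shell_definition() for ",
         "the ion species")
  n_f <- nrow(ion_positions)
  if (is.matrix(solvent)) solvent <- rep(list(solvent), n_f)
  stopifnot(length(solvent) == n_f)

  r1sq <- shells$first_shell_radius^2
  r2sq <- shells$second_shell_radius^2
  per_frame <- t(vapply(seq_len(n_f), function(i) {
    if (nrow(solvent[[i]]) == 0) return(c(0, 0))
    d2 <- .dist2_pbc(ion_positions[i, ], solvent[[i]], box)
    c(sum(d2 <= r1sq), sum(d2 > r1sq & d2 <= r2sq))
  }, numeric(2)))

  zi <- ion_positions[, 3]
  if (is.null(z_breaks)) {
    rng <- range(zi)
    z_breaks <- seq(floor(rng[1] / 0.1) * 0.1,
                    ceiling(rng[2] / 0.1) * 0.1 + 1e-9, by = 0.1)
    if (length(z_breaks) < 2)               # all ions on one plane
      z_breaks <- c(rng[1] - 0.05, rng[1] + 0.05)
  }
  idx <- findInterval(zi, z_breaks, rightmost.closed = TRUE)
  keep <- idx >= 1 & idx < length(z_breaks) + 1
  centers <- (z_breaks[-1] + z_breaks[-length(z_breaks)]) / 2
  used <- sort(unique(idx[keep]))
  out <- data.frame(
    z = centers[used],
    n1 = vapply(used, function(b) mean(per_frame[idx == b, 1]),
                numeric(1)),
    n2 = vapply(used, function(b) mean(per_frame[idx == b, 2]),
                numeric(1)),
    n_frames = vapply(used, function(b) sum(idx == b), numeric(1)))
  structure(out, frames = per_frame, shells = shells,
            class = c("hydration_profile", "data.frame"))
}

#' Retained hydration fraction relative to bulk
#'
#' Divides a hydration-number profile by its bulk value, where the bulk
#' is either a declared axial range (mean of the profile there) or a
#' number.  Used to ask, e.g., whether an ion keeps more than 85% of its
#' first shell across the pore.
#'
#' @param profile numeric profile values, or a `hydration_profile` (then
#'   `column` selects `n1` or `n2`).
#' @param bulk either a single bulk value or `c(z_lo, z_hi)` declaring
#'   the bulk axial range.
#' @param column which count column of a `hydration_profile` to use.
#' @return numeric vector of fractions (profile / bulk).
#' @export
retained_fraction <- function(profile, bulk, column = c("n1", "n2")) {
  column <- match.arg(column)
  if (inherits(profile, "hydration_profile")) {
    z <- profile$z
    vals <- profile[[column]]
  } else {
    vals <- as.numeric(profile)
    z <- seq_along(vals)
  }
  bulk_value <- if (length(bulk) == 2) {
    sel <- z >= bulk[1] & z <= bulk[2]
    if (!any(sel)) stop("no profile bins inside the declared bulk range")
    mean(vals[sel])
  } else bulk
  if (!is.finite(bulk_value) || bulk_value == 0)
    stop("bulk hydration value is zero or undefined")
  vals / bulk_value
}

#' Pore-radius profile (on-axis inscribed sphere)
#'
#' For each grid plane `z`, the pore radius is the largest sphere
#' centered on the axis at `(0, 0, z)` that touches no atom:
#' `R(z) = min_i (axial distance of atom i) - radius_i` over atoms whose
#' z lies within `slab_half_width` of the plane, clipped at zero.  A
#' simplified on-axis variant of the usual channel-radius search: it
#' underestimates the radius of non-axisymmetric pores.  Planes with an
#' empty slab are reported as `NA` (missing, not zero).  With multiple
#' frames the profile is frame-averaged with a standard error.
#'
#' @param atoms data.frame or matrix with columns `x`, `y`, `z`,
#'   `radius` (nm), or a list of such frames.
#' @param z_grid axial grid in nm (strictly increasing).
#' @param slab_half_width slab half-width in nm (default 0.1).
#' @return data.frame of class `radius_profile` with `z`, `R` (nm),
#'   `se` (`NA` for a single frame) and `n_atoms`.
#' @export
pore_radius_profile <- function(atoms, z_grid, slab_half_width = 0.1) {
  stopifnot(all(diff(z_grid) > 0), slab_half_width > 0)
  frames <- if (is.data.frame(atoms) || is.matrix(atoms)) list(atoms)
            else atoms
  one_frame <- function(fr) {
    fr <- as.data.frame(fr)
    stopifnot(all(c("x", "y", "z", "radius") %in% names(fr)))
    vapply(z_grid, function(zz) {
      sel <- abs(fr$z - zz) <= slab_half_width
      if (!any(sel)) return(NA_real_)
      max(0, min(sqrt(fr$x[sel]^2 + fr$y[sel]^2) - fr$radius[sel]))
    }, numeric(1))
  }
  counts <- vapply(z_grid, function(zz)
    sum(vapply(frames, function(fr)
      sum(abs(as.data.frame(fr)$z - zz) <= slab_half_width),
      numeric(1))), numeric(1))
  mat <- vapply(frames, one_frame, numeric(length(z_grid)))
  mat <- matrix(mat, nrow = length(z_grid))
  R <- rowMeans(mat, na.rm = TRUE)
  R[is.nan(R)] <- NA_real_
  se <- if (length(frames) > 1)
    apply(mat, 1, function(v) {
      v <- v[is.finite(v)]
      if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
    })
  else rep(NA_real_, length(z_grid))
  structure(data.frame(z = z_grid, R = R, se = se, n_atoms = counts),
            class = c("radius_profile", "data.frame"))
}
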