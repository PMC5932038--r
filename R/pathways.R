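# Exit-pathway classification of pore-passing ion trajectories into the
# three observed modes -- A: central axial exit, B: cleft entry followed
# by an axial exit, C: lateral exit through a cleft -- plus an
# "unclassified" branch for ambiguous recrossing paths.

#' Cylindrical coordinates of a trajectory
#'
#' Projects a 3-D trajectory onto the channel axis: `z` is the axial
#' coordinate and `r` the perpendicular distance to the axis.  The axis
#' is given as a point and direction; the default is the z axis through
#' the origin.
#'
#' @param traj an [ion_trajectory()] or an n x 3 position matrix
#'   (positions must be unwrapped in z).
#' @param axis_point point on the axis (nm).
#' @param axis_direction axis direction vector (normalised internally).
#' @return data.frame with columns `time` (if available), `z` and `r`
#'   (nm).
#' @examples
#' to_cylindrical(matrix(c(3, 4, 2), nrow = 1))  # r = 5
#' @export
to_cylindrical <- function(traj, axis_point = c(0, 0, 0),
                           axis_direction = c(0, 0, 1)) {
  pos <- if (inherits(traj, "ion_trajectory")) traj$positions
         else as.matrix(traj)
  stopifnot(ncol(pos) == 3)
  u <- axis_direction / sqrt(sum(axis_direction^2))
  rel <- sweep(pos, 2, axis_point)
  z <- as.numeric(rel %*% u)
  perp <- rel - outer(z, u)
  r <- sqrt(rowSums(perp^2))
  out <- data.frame(z = z, r = r)
  if (inherits(traj, "ion_trajectory")) out <- cbind(time = traj$times,
                                                     out)
  out
}

#' Classify the exit pathway of one pore-passing trajectory
#'
#' Region-sequence rules on the cylindrical track `(z(t), r(t))` against
#' a [channel_geometry()].  Writing "band" for `z_basin2 < z < z_top`:
#'
#' * **C** (lateral): `r` exceeds `r_lateral` inside the band before any
#'   upward crossing of `z_top`.
#' * **A** (central axial): the trajectory ends beyond `z_top`, and `r`
#'   never exceeded `r_cleft` inside the band up to the last upward
#'   `z_top` crossing.
#' * **B** (cleft then axial): as A but with at least one cleft visit
#'   (`r > r_cleft` in the band); `r` at the last `z_top` crossing must
#'   still be below `r_lateral`.
#' * **unclassified**: the trajectory ends inside the band/cleft, or its
#'   final `z_top` crossing happens at `r >= r_lateral`.
#'
#' Only the final committed exit determines the label: frames after the
#' last upward `z_top` crossing cannot revoke it.  A trajectory that
#' never visits `z < z_lumen` before reaching `z > z_basin2` is not
#' pore-passing and raises an error of class `permeon_reject`.
#'
#' @param traj an [ion_trajectory()] or a data.frame with `z` and `r`
#'   columns (see [to_cylindrical()]).
#' @param geometry a [channel_geometry()].
#' @return an object of class `pathway_label`: `label` (factor level of
#'   `A`, `B`, `C`, `unclassified`) and `trace` (run-length region-visit
#'   sequence).
#' @export
classify_exit <- function(traj, geometry) {
  stopifnot(inherits(geometry, "channel_geometry"))
  cyl <- if (is.data.frame(traj)) traj else to_cylindrical(traj)
  z <- cyl$z; r <- cyl$r
  g <- geometry

  first_deep <- match(TRUE, z < g$z_lumen)
  first_past <- match(TRUE, z > g$z_basin2)
  if (is.na(first_deep) || is.na(first_past) || first_deep > first_past)
    stop(structure(class = c("permeon_reject", "error", "condition"),
                   list(message = paste0(
                     "trajectory does not pass the pore (no visit below ",
                     "z_lumen preceding z_basin2)"), call = NULL)))

  band <- z > g$z_basin2 & z < g$z_top
  up <- which(z[-1] > g$z_top & z[-length(z)] <= g$z_top) + 1L
  first_top <- if (length(up)) up[1] else Inf

  region <- ifelse(z <= g$z_lumen, "lumen",
            ifelse(z <= g$z_basin2, "pore",
            ifelse(z >= g$z_top, "cytoplasm",
            ifelse(r > g$r_lateral, "lateral",
            ifelse(r > g$r_cleft, "cleft", "band_axial")))))
  trace <- rle(region)$values

  lateral_hit <- any(band & r > g$r_lateral &
                       seq_along(z) < first_top)
  label <-
    if (lateral_hit) {
      "C"
    } else if (z[length(z)] > g$z_top && length(up)) {
      last_top <- up[length(up)]
      if (r[last_top] >= g$r_lateral) {
        "unclassified"
      } else if (any(band & r > g$r_cleft &
                     seq_along(z) <= last_top)) "B" else "A"
    } else {
      "unclassified"
    }
  structure(list(label = factor(label, levels = .pathway_levels),
                 trace = trace),
            class = "pathway_label")
}

.pathway_levels <- c("A", "B", "C", "unclassified")

#' @export
print.pathway_label <- function(x, ...) {
  cat("pathway", as.character(x$label), "| trace:",
      paste(x$trace, collapse = " > "), "\n")
  invisible(x)
}

#' Classify an ensemble of trajectories
#'
#' Applies [classify_exit()] to every trajectory; non-pore-passing
#' trajectories are collected separately and excluded from fraction
#' reporting.
#'
#' @param trajectories list of [ion_trajectory()] (or cylindrical
#'   data.frames).
#' @param geometry a [channel_geometry()].
#' @return list with `labels` (factor), `traces`, and `rejected`
#'   (indices with the rejection reasons).
#' @export
classify_ensemble <- function(trajectories, geometry) {
  labels <- character(0); traces <- list(); rej <- list()
  keep_id <- integer(0)
  for (i in seq_along(trajectories)) {
    res <- tryCatch(classify_exit(trajectories[[i]], geometry),
                    permeon_reject = function(e) e)
    if (inherits(res, "permeon_reject")) {
      rej[[length(rej) + 1]] <- list(index = i,
                                     reason = conditionMessage(res))
    } else {
      keep_id <- c(keep_id, i)
      labels <- c(labels, as.character(res$label))
      traces[[length(traces) + 1]] <- res$trace
    }
  }
  list(labels = factor(labels, levels = .pathway_levels),
       traces = traces, indices = keep_id, rejected = rej)
}

#' Pathway fraction report
#'
#' Counts and fractions per exit mode over the pore-passing
#' trajectories, with exact binomial 95% confidence intervals per label.
#'
#' @param labels factor or character vector of labels in
#'   `A`/`B`/`C`/`unclassified` (e.g. from [classify_ensemble()]).
#' @param conf_level confidence level for the exact binomial intervals.
#' @return an object of class `pathway_report`: data.frame with
#'   `label`, `count`, `fraction`, `ci_lo`, `ci_hi`; attribute `total`.
#' @examples
#' pathway_report(rep(c("A", "B", "C", "unclassified"),
#'                    c(53, 25, 17, 5)))
#' @export
pathway_report <- function(labels, conf_level = 0.95) {
  if (length(labels) == 0)
    stop("no labels: cannot report fractions of an empty ensemble")
  labels <- factor(as.character(labels), levels = .pathway_levels)
  if (anyNA(labels)) stop("labels must be A, B, C or unclassified")
  n <- length(labels)
  counts <- table(labels)
  ci <- t(vapply(as.integer(counts), function(k)
    binom.test(k, n, conf.level = conf_level)$conf.int, numeric(2)))
  out <- data.frame(label = names(counts), count = as.integer(counts),
                    fraction = as.numeric(counts) / n,
                    ci_lo = ci[, 1], ci_hi = ci[, 2])
  structure(out, total = n, conf_level = conf_level,
            class = c("pathway_report", "data.frame"))
}

#' @export
print.pathway_report <- function(x, ...) {
  cat(sprintf("exit-pathway report (%d pore-passing trajectories):\n",
              attr(x, "total")))
  df <- as.data.frame(x)
  df$fraction <- sprintf("%.1f%%", 100 * df$fraction)
  df$ci_lo <- sprintf("%.3f", df$ci_lo)
  df$ci_hi <- sprintf("%.3f", df$ci_hi)
  print(df, row.names = FALSE)
  invisible(x)
}
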