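#' Per-ion 3-D trajectory
#'
#' Container for one ion's position time series with its box, charge and
#' wrapping convention; the basis for crossing counting, pathway
#' classification and hydration analysis.
#'
#' @param ion_id identifier (integer or character).
#' @param times strictly increasing times in ns.
#' @param positions n x 3 numeric matrix (x, y, z) in nm.
#' @param box box lengths `c(Lx, Ly, Lz)` in nm.
#' @param charge charge in elementary charges.
#' @param wrapped logical; positions wrapped into the box.
#' @param species optional species tag.
#' @return an object of class `ion_trajectory`.
#' @export
ion_trajectory <- function(ion_id, times, positions, box, charge = 1,
                           wrapped = TRUE, species = NULL) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, nrow(positions) == length(times),
            length(box) == 3, all(box > 0))
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (wrapped) {
    for (k in 1:3)
      if (any(positions[, k] < -1e-9 | positions[, k] > box[k] + 1e-9))
        stop("wrapped_flag set but positions fall outside the box in ",
             c("x", "y", "z")[k])
  }
  structure(list(ion_id = ion_id, times = as.numeric(times),
                 positions = positions, box = as.numeric(box),
                 charge = charge, wrapped = wrapped, species = species),
            class = "ion_trajectory")
}

#' @export
print.ion_trajectory <- function(x, ...) {
  cat(sprintf(
    "ion trajectory %s: %d frames over %.3g ns, q = %+g e, box %s nm%s\n",
    as.character(x$ion_id), length(x$times), diff(range(x$times)),
    x$charge, paste(signif(x$box, 4), collapse = " x "),
    if (x$wrapped) " (wrapped)" else " (unwrapped)"))
  invisible(x)
}

# Minimum-image unwrapping of a wrapped 1-D coordinate series.
.unwrap <- function(z, L) {
  if (length(z) < 2) return(z)
  dz <- diff(z)
  dz <- dz - L * round(dz / L)
  c(z[1], z[1] + cumsum(dz))
}
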