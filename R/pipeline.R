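# Run manifests and the end-to-end pipeline: umbrella windows -> PMF ->
# binding; permeation runs -> currents -> IV -> pathways; snapshots ->
# pore-radius profile.

#' Read and validate a run manifest
#'
#' A YAML file with a `settings` block (temperature, periodic_length,
#' n_bins, discard_ns, seed, n_boot, bulk_interval, bound_interval,
#' area, geometry, radius_grid) and a `datasets` list whose entries have
#' `path` and `kind` in `umbrella_window`, `permeation_run` (with
#' `voltage` or `field`), or `snapshot`.  Every referenced path must
#' exist; metadata must be complete for its kind.
#'
#' @param path YAML manifest path.
#' @return an object of class `run_manifest`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such manifest: ", path)
  man <- yaml::read_yaml(path)
  if (is.null(man$datasets) || length(man$datasets) == 0)
    stop("manifest has no datasets")
  base <- dirname(path)
  kinds <- c("umbrella_window", "permeation_run", "snapshot")
  for (i in seq_along(man$datasets)) {
    d <- man$datasets[[i]]
    if (is.null(d$path) || is.null(d$kind))
      stop("dataset entry ", i, " lacks path or kind")
    if (!d$kind %in% kinds)
      stop("dataset entry ", i, ": unknown kind '", d$kind, "'")
    p <- file.path(base, d$path)
    if (!file.exists(p))
      stop("dataset entry ", i, " references missing path: ", p)
    man$datasets[[i]]$path <- p
    if (d$kind == "permeation_run" &&
        is.null(d$voltage) && is.null(d$field))
      stop("permeation_run entry ", i, " needs voltage or field")
  }
  man$settings <- utils::modifyList(
    list(temperature = 300, periodic_length = NULL, n_bins = 200,
         discard_ns = 10, seed = 1, n_boot = 0,
         bulk_interval = NULL, bound_interval = NULL, area = NULL,
         geometry = NULL, radius_grid = NULL),
    if (is.null(man$settings)) list() else man$settings)
  structure(man, class = "run_manifest")
}

.provenance <- function(settings, inputs) {
  c(sprintf("# permeon %s", as.character(packageVersion("permeon"))),
    sprintf("# seed %s", settings$seed),
    sprintf("# inputs: %s", paste(basename(inputs), collapse = ", ")),
    sprintf("# temperature %g K", settings$temperature))
}

.write_stage_csv <- function(df, path, settings, inputs) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance(settings, inputs), con)
  write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline from a manifest
#'
#' Executes, for whichever dataset kinds the manifest provides:
#' umbrella windows -> (cyclic) WHAM PMF with optional bootstrap errors
#' -> standard binding free energy; permeation runs -> per-run currents
#' -> IV fit -> exit-pathway classification (unwrapped runs with a
#' geometry); snapshots -> pore-radius profile.  Stages without inputs
#' are reported as skipped.  Outputs are deterministic given the
#' manifest seed; when `out_dir` is given every stage writes CSV/XVG
#' results with a provenance header (package version, seed, inputs,
#' parameters).
#'
#' @param manifest a [read_manifest()] result or path to a manifest.
#' @param out_dir optional output directory.
#' @return list with elements `pmf`, `binding`, `currents`, `iv`,
#'   `pathways`, `radius` (those not run are `NULL`) and `skipped`.
#' @export
run_pipeline <- function(manifest, out_dir = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(inherits(manifest, "run_manifest"))
  s <- manifest$settings
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  kinds <- vapply(manifest$datasets, `[[`, character(1), "kind")
  paths <- vapply(manifest$datasets, `[[`, character(1), "path")
  out <- list(pmf = NULL, binding = NULL, currents = NULL, iv = NULL,
              pathways = NULL, radius = NULL, skipped = character(0))
  fail <- function(stage, e)
    stop("pipeline stage '", stage, "' failed: ",
         conditionMessage(e), call. = FALSE)

  # --- umbrella -> PMF -> binding ------------------------------------
  if (any(kinds == "umbrella_window")) {
    out$pmf <- tryCatch({
      wm <- paths[kinds == "umbrella_window"][1]
      windows <- read_umbrella_xvg(wm, periodic_length =
                                         s$periodic_length)
      ref <- if (!is.null(s$bulk_interval)) "bulk_zero" else "min_zero"
      bulk <- if (!is.null(s$bulk_interval)) unlist(s$bulk_interval)
      if (s$n_boot >= 2)
        bootstrap_pmf(windows, n_bins = s$n_bins,
                      temperature = s$temperature,
                      periodic_length = s$periodic_length,
                      reference = ref, bulk_interval = bulk,
                      n_boot = s$n_boot, seed = s$seed)
      else
        solve_wham(windows, n_bins = s$n_bins,
                   temperature = s$temperature,
                   periodic_length = s$periodic_length,
                   reference = ref, bulk_interval = bulk)
    }, error = function(e) fail("wham", e))
    if (!is.null(s$bound_interval) && !is.null(s$area) &&
        out$pmf$reference == "bulk_zero") {
      out$binding <- tryCatch(
        standard_binding_free_energy(out$pmf,
                                     unlist(s$bound_interval),
                                     s$area),
        error = function(e) fail("binding", e))
    } else out$skipped <- c(out$skipped, "binding")
    if (!is.null(out_dir)) {
      write_xvg(cbind(out$pmf$bin_centers, out$pmf$W, out$pmf$errors),
                file.path(out_dir, "pmf.xvg"),
                comments = c(.provenance(s, paths[kinds ==
                                                    "umbrella_window"]),
                             '@ xaxis label "z (nm)"',
                             '@ yaxis label "W (kJ/mol)"'))
      .write_stage_csv(data.frame(z = out$pmf$bin_centers,
                                  W = out$pmf$W,
                                  error = out$pmf$errors),
                       file.path(out_dir, "pmf.csv"), s,
                       paths[kinds == "umbrella_window"])
      if (!is.null(out$binding))
        .write_stage_csv(
          data.frame(dG0_kJ_mol = out$binding$dG0,
                     dG0_error = out$binding$dG0_error,
                     area_nm2 = out$binding$area,
                     boltzmann_integral_nm =
                       out$binding$boltzmann_integral),
          file.path(out_dir, "binding.csv"), s,
          paths[kinds == "umbrella_window"])
    }
  } else out$skipped <- c(out$skipped, "wham", "binding")

  # --- permeation -> current -> IV -> pathways -----------------------
  # Crossing counting presumes a wrapped periodic-box run; unwrapped
  # runs feed the pathway classifier instead.
  if (any(kinds == "permeation_run")) {
    runs <- which(kinds == "permeation_run")
    loaded <- tryCatch(lapply(runs, function(i) {
      d <- manifest$datasets[[i]]
      trajs <- read_trajectory_table(d$path)
      Lz <- trajs[[1]]$box[3]
      V <- if (!is.null(d$voltage)) d$voltage
           else voltage_from_field(d$field, Lz)
      list(trajs = trajs, voltage = V, path = d$path,
           wrapped = trajs[[1]]$wrapped)
    }), error = function(e) fail("current", e))
    wrapped_runs <- Filter(function(x) x$wrapped, loaded)
    cur <- tryCatch(lapply(wrapped_runs, function(run) {
      tab <- run_current(run$trajs, discard = s$discard_ns)
      tot <- tab[tab$species == "total", ]
      list(point = data.frame(voltage = run$voltage,
                              current = tot$current_pA,
                              current_error = tot$error_pA),
           table = cbind(run = basename(run$path), tab))
    }), error = function(e) fail("current", e))
    out$currents <- do.call(rbind, lapply(cur, `[[`, "table"))
    iv_points <- do.call(rbind, lapply(cur, `[[`, "point"))
    if (!is.null(iv_points) &&
        length(unique(iv_points$voltage)) >= 2) {
      out$iv <- tryCatch(fit_iv(iv_points),
                         error = function(e) fail("iv", e))
    } else out$skipped <- c(out$skipped, "iv")
    geom <- if (!is.null(s$geometry))
      do.call(channel_geometry, s$geometry)
    unwrapped <- unlist(lapply(loaded, function(cc)
      Filter(function(tr) !tr$wrapped, cc$trajs)), recursive = FALSE)
    if (!is.null(geom) && length(unwrapped) > 0) {
      out$pathways <- tryCatch({
        cls <- classify_ensemble(unwrapped, geom)
        pathway_report(cls$labels)
      }, error = function(e) fail("pathways", e))
    } else out$skipped <- c(out$skipped, "pathways")
    if (!is.null(out_dir)) {
      if (!is.null(out$currents))
        .write_stage_csv(out$currents,
                         file.path(out_dir, "currents.csv"), s,
                         paths[runs])
      if (!is.null(iv_points))
        .write_stage_csv(iv_points,
                         file.path(out_dir, "iv_points.csv"),
                         s, paths[runs])
      if (!is.null(out$iv))
        .write_stage_csv(
          data.frame(conductance_pS = out$iv$conductance_pS,
                     se_pS = out$iv$se_pS,
                     intercept_pA = out$iv$intercept_pA,
                     r_squared = out$iv$r_squared),
          file.path(out_dir, "iv_fit.csv"), s, paths[runs])
      if (!is.null(out$pathways))
        .write_stage_csv(as.data.frame(out$pathways),
                         file.path(out_dir, "pathways.csv"), s,
                         paths[runs])
    }
  } else out$skipped <- c(out$skipped, "current", "iv", "pathways")

  # --- snapshots -> pore radius --------------------------------------
  if (any(kinds == "snapshot") && !is.null(s$radius_grid)) {
    snaps <- paths[kinds == "snapshot"]
    out$radius <- tryCatch({
      frames <- lapply(snaps, read_snapshot)
      grid <- seq(s$radius_grid[[1]], s$radius_grid[[2]],
                  by = s$radius_grid[[3]])
      pore_radius_profile(frames, grid)
    }, error = function(e) fail("radius", e))
    if (!is.null(out_dir))
      .write_stage_csv(as.data.frame(out$radius),
                       file.path(out_dir, "radius.csv"), s, snaps)
  } else if (any(kinds == "snapshot")) {
    out$skipped <- c(out$skipped, "radius")
  } else out$skipped <- c(out$skipped, "radius")

  out
}

#' Read a coordinate snapshot for pore-radius profiling
#'
#' Accepts either a CSV/TSV with columns `x`, `y`, `z`, `radius` (nm)
#' or a GRO file, in which case per-atom radii are assigned from a
#' small van-der-Waals lookup by element (first letter of the atom
#' name: H 0.120, C 0.170, N 0.155, O 0.152, S 0.180 nm).
#'
#' @param path snapshot path.
#' @return data.frame with `x`, `y`, `z`, `radius`.
#' @export
read_snapshot <- function(path) {
  if (grepl("\\.gro$", path)) {
    df <- read_gro(path)
    vdw <- c(H = 0.120, C = 0.170, N = 0.155, O = 0.152, S = 0.180)
    el <- substr(df$atom, 1, 1)
    r <- unname(vdw[el])
    r[is.na(r)] <- 0.17
    return(data.frame(x = df$x, y = df$y, z = df$z, radius = r))
  }
  df <- read.table(path, header = TRUE,
                   sep = if (grepl("\\.tsv$", path)) "\t" else ",",
                   comment.char = "#")
  stopifnot(all(c("x", "y", "z", "radius") %in% names(df)))
  df
}
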