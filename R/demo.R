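# Self-contained synthetic study: writes every input class (umbrella
# XVGs, applied-voltage runs, a pathway ensemble, a snapshot) plus a
# manifest, so the full pipeline can be exercised from files on disk.

#' Build a small synthetic demonstration dataset
#'
#' Generates, with known ground truth, (i) umbrella windows on a
#' periodic single-well landscape with a genuine flat bulk region,
#' (ii) applied-voltage permeation runs on a flat landscape at three
#' voltages, (iii) an unwrapped labelled pathway ensemble, and (iv) a
#' cylindrical-wall snapshot -- and writes them under `dir` together
#' with a `manifest.yaml` that [run_pipeline()] consumes.
#'
#' @param dir output directory (created).
#' @param seed integer seed; the whole dataset is deterministic in it.
#' @param n_windows umbrella windows.
#' @param n_steps_window samples per umbrella window.
#' @param n_ions ions per applied-voltage run.
#' @param n_steps_run integration steps per applied-voltage run.
#' @param n_pathway pathway-ensemble size.
#' @return the manifest path, invisibly; attribute `truth` carries the
#'   generating parameters (potential, well depth, voltages).
#' @export
build_demo_dataset <- function(dir, seed = 1, n_windows = 41,
                               n_steps_window = 6000, n_ions = 8,
                               n_steps_run = 40000, n_pathway = 80) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  L <- 6
  pot <- gaussian_wells_potential(centers = 2, depths = 8,
                                  sigma = 0.3, length = L)
  windows <- generate_umbrella_dataset(
    pot, n_windows = n_windows, spacing = L / n_windows, k = 500,
    params = sim_params(n_steps = n_steps_window, dt = 2e-4,
                        box_length = L, seed = seed),
    perp_spread = c(1.2, 1.2))
  write_umbrella_xvg(windows, file.path(dir, "umbrella"), dt = 2e-4)

  voltages <- c(-0.2, 0.2, 0.5)
  run_paths <- character(0)
  for (i in seq_along(voltages)) {
    pars <- sim_params(n_steps = n_steps_run, dt = 1e-3,
                       box_length = 14.626,
                       field = field_from_voltage(voltages[i]),
                       charge = 1, seed = seed + i)
    trajs <- simulate_field_ensemble(pars, n_ions = n_ions,
                                     sample_every = 10)
    p <- file.path(dir, sprintf("run_%+.1fV.tsv", voltages[i]))
    write_trajectory_table(trajs, p)
    run_paths <- c(run_paths, p)
  }

  geom <- channel_geometry()
  ens <- generate_permeation_ensemble(
    geom, sim_params(n_steps = 1, dt = 0.01,
                     field = field_from_voltage(0.3),
                     seed = seed + 100),
    pathway_fractions = c(0.53, 0.25, 0.17), n_ions = n_pathway)
  ppath <- file.path(dir, "pathways_0.3V.tsv")
  write_trajectory_table(ens, ppath)

  # cylindrical wall, bore 0.8 nm, atom radius 0.15 nm
  zs <- rep(seq(-3, 3, by = 0.1), each = 16)
  ang <- rep(seq(0, 2 * pi, length.out = 17)[-17],
             times = length(unique(zs)))
  snap <- data.frame(x = 0.8 * cos(ang), y = 0.8 * sin(ang), z = zs,
                     radius = 0.15)
  spath <- file.path(dir, "wall_snapshot.csv")
  write.table(snap, spath, sep = ",", row.names = FALSE, quote = FALSE)

  manifest <- list(
    settings = list(temperature = 300, periodic_length = L,
                    n_bins = 120, discard_ns = 10, seed = seed,
                    n_boot = 0,
                    bulk_interval = c(4.2, 5.8),
                    bound_interval = c(0.8, 3.2), area = 9.09,
                    geometry = list(z_lumen = geom$z_lumen,
                                    z_basin2 = geom$z_basin2,
                                    z_top = geom$z_top,
                                    r_cleft = geom$r_cleft,
                                    r_lateral = geom$r_lateral),
                    radius_grid = c(-2, 2, 0.2)),
    datasets = c(
      list(list(path = "umbrella/windows.csv",
                kind = "umbrella_window")),
      lapply(seq_along(voltages), function(i)
        list(path = basename(run_paths[i]), kind = "permeation_run",
             voltage = voltages[i])),
      list(list(path = basename(ppath), kind = "permeation_run",
                voltage = 0.3),
           list(path = basename(spath), kind = "snapshot"))))
  mpath <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, mpath)
  attr(mpath, "truth") <- list(potential = pot, well_depth = 8,
                               voltages = voltages, bore = 0.8,
                               atom_radius = 0.15)
  invisible(mpath)
}
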