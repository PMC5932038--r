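# Readers and writers for the plain-text formats of the pull-coordinate
# ecosystem: XVG tables (comment lines '#', directive lines '@'),
# tabular trajectory files and GRO coordinate snapshots.

#' Read an XVG table
#'
#' Parses a pull-coordinate-style XVG file: lines starting with `#` or
#' `@` are preamble (preserved, never parsed as data); all remaining
#' lines must be whitespace-separated numbers with a constant column
#' count.  Decimal parsing is locale-independent.
#'
#' @param path file path.
#' @return an object of class `xvg_table`: numeric matrix with
#'   attributes `preamble` (character) and `labels` (from `@ s<i>
#'   legend` directives, when present).
#' @export
read_xvg <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  is_comment <- grepl("^[ \t]*[#@]", lines)
  blank <- grepl("^[ \t]*$", lines)
  data_lines <- lines[!is_comment & !blank]
  if (length(data_lines) == 0)
    stop("empty data: ", path, " contains only comments/directives")
  toks <- strsplit(trimws(data_lines), "[ \t]+")
  ncols <- lengths(toks)
  if (length(unique(ncols)) != 1) {
    bad <- which(ncols != ncols[1])[1]
    lineno <- which(!is_comment & !blank)[bad]
    stop("ragged row in ", path, " at line ", lineno, ": ",
         ncols[bad], " fields, expected ", ncols[1])
  }
  vals <- suppressWarnings(as.numeric(unlist(toks)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    lineno <- which(!is_comment & !blank)[ceiling(bad / ncols[1])]
    stop("non-numeric field in ", path, " at line ", lineno)
  }
  m <- matrix(vals, ncol = ncols[1], byrow = TRUE)
  legends <- regmatches(lines,
    regexpr('@ *s[0-9]+ +legend +"[^"]*"', lines))
  labels <- sub('.*legend +"([^"]*)".*', "\\1", legends)
  structure(m, preamble = lines[is_comment],
            labels = if (length(labels)) labels else NULL,
            class = c("xvg_table", "matrix", "array"))
}

#' Write an XVG table
#'
#' @param x numeric matrix or data.frame.
#' @param path output path.
#' @param comments character vector written as `#`/`@` preamble lines
#'   (prefixes added when absent).
#' @param digits significant digits (default 17: round-trip exact).
#' @return `path`, invisibly.
#' @export
write_xvg <- function(x, path, comments = character(0), digits = 17) {
  x <- as.matrix(x)
  pre <- ifelse(grepl("^[#@]", comments), comments,
                paste("#", comments))
  rows <- apply(x, 1, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = " "))
  writeLines(c(pre, rows), path)
  invisible(path)
}

#' Write umbrella windows as XVG pull-coordinate files
#'
#' One file per window (`pullx_<i>.xvg`: time and reaction coordinate;
#' in-plane samples appended as extra columns when present) plus a
#' manifest CSV (`windows.csv`: path, center, k, discard_fraction).
#'
#' @param windows an `umbrella_set`.
#' @param dir output directory (created).
#' @param dt sampling interval for the time column in ns.
#' @return path of the manifest CSV, invisibly.
#' @export
write_umbrella_xvg <- function(windows, dir, dt = 2e-4) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(windows))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    paths[i] <- file.path(dir, sprintf("pullx_%03d.xvg", i))
    m <- cbind(seq_along(w$samples) * dt, w$samples)
    if (!is.null(w$perp_samples)) m <- cbind(m, w$perp_samples)
    write_xvg(m, paths[i], comments = c(
      sprintf("# umbrella window %d: center %.17g nm, k %.17g kJ/mol/nm^2",
              i, w$center, w$k),
      '@ xaxis label "time (ns)"', '@ yaxis label "z (nm)"'))
  }
  manifest <- data.frame(
    path = basename(paths),
    center = vapply(windows, `[[`, numeric(1), "center"),
    k = vapply(windows, `[[`, numeric(1), "k"),
    discard_fraction = vapply(windows, `[[`, numeric(1),
                              "discard_fraction"))
  mpath <- file.path(dir, "windows.csv")
  write.table(manifest, mpath, sep = ",", row.names = FALSE,
              quote = FALSE)
  invisible(mpath)
}

#' Read umbrella windows from XVG files and a window manifest
#'
#' @param manifest_csv CSV with columns `path`, `center`, `k` and
#'   optionally `discard_fraction`; paths are relative to the CSV.
#' @param periodic_length periodic length attached to the set, or
#'   `NULL`.
#' @return an `umbrella_set`.
#' @export
read_umbrella_xvg <- function(manifest_csv, periodic_length = NULL) {
  man <- read.table(manifest_csv, sep = ",", header = TRUE,
                    stringsAsFactors = FALSE)
  stopifnot(all(c("path", "center", "k") %in% names(man)))
  base <- dirname(manifest_csv)
  windows <- lapply(seq_len(nrow(man)), function(i) {
    p <- file.path(base, man$path[i])
    if (!file.exists(p)) stop("manifest references missing file: ", p)
    m <- read_xvg(p)
    umbrella_window(center = man$center[i], k = man$k[i],
                    samples = m[, 2],
                    perp_samples = if (ncol(m) >= 4) m[, 3:4] else NULL,
                    discard_fraction =
                      if ("discard_fraction" %in% names(man))
                        man$discard_fraction[i] else 1 / 6)
  })
  structure(windows, class = c("umbrella_set", "list"),
            periodic_length = periodic_length)
}

#' Write / read permeation trajectories as tabular text
#'
#' Long-format TSV with columns `time`, `ion_id`, `x`, `y`, `z`; box,
#' charge and wrapping recorded in `#` header lines and restored on
#' read.
#'
#' @param trajectories list of [ion_trajectory()].
#' @param path TSV path.
#' @return `write_trajectory_table`: `path`, invisibly;
#'   `read_trajectory_table`: list of [ion_trajectory()].
#' @export
write_trajectory_table <- function(trajectories, path) {
  tr1 <- trajectories[[1]]
  header <- c(sprintf("# box_nm %.17g %.17g %.17g", tr1$box[1],
                      tr1$box[2], tr1$box[3]),
              sprintf("# charge_e %.17g", tr1$charge),
              sprintf("# wrapped %d", as.integer(tr1$wrapped)),
              "# time\tion_id\tx\ty\tz")
  rows <- do.call(rbind, lapply(trajectories, function(tr)
    data.frame(time = tr$times, ion_id = tr$ion_id,
               x = tr$positions[, 1], y = tr$positions[, 2],
               z = tr$positions[, 3])))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(format(rows, digits = 17, trim = TRUE, scientific = NA),
              con, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_table
#' @export
read_trajectory_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[grepl("^#", lines)]
  getv <- function(key, n) {
    ln <- hdr[grepl(paste0("^# ", key, " "), hdr)]
    if (!length(ln)) return(NULL)
    as.numeric(strsplit(trimws(sub(paste0("^# ", key), "", ln[1])),
                        "[ \t]+")[[1]][seq_len(n)])
  }
  box <- getv("box_nm", 3)
  charge <- getv("charge_e", 1)
  wrapped <- getv("wrapped", 1)
  df <- read.table(text = lines[!grepl("^#", lines)], sep = "\t",
                   col.names = c("time", "ion_id", "x", "y", "z"))
  lapply(split(df, df$ion_id), function(d)
    ion_trajectory(ion_id = d$ion_id[1], times = d$time,
                   positions = as.matrix(d[, c("x", "y", "z")]),
                   box = if (is.null(box)) rep(Inf, 3) else box,
                   charge = if (is.null(charge)) 1 else charge,
                   wrapped = !is.null(wrapped) && wrapped == 1))
}

#' Read a GRO coordinate snapshot
#'
#' Fixed-column GRO dialect: title line, atom count, atom records
#' (residue number/name, atom name, atom number, x y z in nm), box line.
#'
#' @param path GRO file path.
#' @return data.frame with `resid`, `resname`, `atom`, `x`, `y`, `z`;
#'   attribute `box` (nm) and `title`.
#' @export
read_gro <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop("truncated GRO file: ", path)
  n <- as.integer(trimws(lines[2]))
  if (is.na(n) || length(lines) < n + 3)
    stop("truncated GRO file: ", path)
  rec <- lines[3:(n + 2)]
  df <- data.frame(
    resid = as.integer(substr(rec, 1, 5)),
    resname = trimws(substr(rec, 6, 10)),
    atom = trimws(substr(rec, 11, 15)),
    x = as.numeric(substr(rec, 21, 28)),
    y = as.numeric(substr(rec, 29, 36)),
    z = as.numeric(substr(rec, 37, 44)))
  box <- as.numeric(strsplit(trimws(lines[n + 3]), "[ \t]+")[[1]])
  attr(df, "box") <- box
  attr(df, "title") <- lines[1]
  df
}
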