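#' Read a PDB file into structure models
#'
#' Parses ATOM/HETATM records (fixed-width columns) with MODEL/ENDMDL
#' boundaries via `bio3d::read.pdb`; residue numbering is kept 1-based as
#' written.  Coordinate fields are pre-validated so a truncated record is
#' reported with its line number.
#'
#' @param path path to a PDB file.
#' @return a single `structure_model`, or a list of them for multi-model
#'   files.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  atom_lines <- grep("^(ATOM|HETATM)", lines)
  for (ln in atom_lines) {
    txt <- lines[ln]
    if (nchar(txt) < 54)
      stop(sprintf("parse error at line %d: truncated ATOM record", ln))
    coords <- c(substr(txt, 31, 38), substr(txt, 39, 46), substr(txt, 47, 54))
    if (any(is.na(suppressWarnings(as.numeric(coords)))))
      stop(sprintf("parse error at line %d: malformed coordinate field", ln))
  }
  if (length(atom_lines) == 0) stop("no ATOM/HETATM records in ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  names <- pdb$atom$elety
  resno <- pdb$atom$resno
  nmod <- nrow(pdb$xyz)
  models <- lapply(seq_len(nmod), function(m)
    structure_model(names, resno,
                    matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)))
  if (nmod == 1) models[[1]] else models
}

#' Write a trajectory as an XYZ file
#'
#' One block per frame: atom count, a comment line
#' `step=<n> t_smt=<fs>` carrying the step index and effective
#' standard-mass time, then one `label x y z` line per atom with 6-decimal
#' coordinates.
#'
#' @param traj a `trajectory`.
#' @param labels per-atom labels; defaults to the trajectory's stored
#'   labels.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(traj, path, labels = NULL) {
  if (is.null(labels)) labels <- traj$labels
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(traj$frames)) {
    fr <- traj$frames[[k]]
    if (is.null(labels)) labels <- rep("X", nrow(fr))
    if (length(labels) != nrow(fr))
      stop("format error: labels length does not match atom count")
    writeLines(c(
      as.character(nrow(fr)),
      sprintf("step=%d t_smt=%.6f", traj$step_indices[k],
              traj$step_indices[k] * traj$effective_dt),
      sprintf("%s %.6f %.6f %.6f", labels, fr[, 1], fr[, 2], fr[, 3])),
      con)
  }
  invisible(path)
}

#' Read an XYZ trajectory written by [write_xyz_trajectory()]
#'
#' @param path input file.
#' @return a `trajectory` (effective time axis recovered from the comment
#'   lines; coordinates at the printed 6-decimal precision).
#' @export
read_xyz_trajectory <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list(); steps <- integer(0); labels <- NULL
  eff_dt <- NA_real_
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(lines[i]))
    if (is.na(n)) stop("format error: expected atom count at line ", i)
    if (i + 1 + n > length(lines))
      stop("format error: truncated frame at line ", i)
    cm <- lines[i + 1]
    step <- as.integer(sub(".*step=([0-9]+).*", "\\1", cm))
    tsmt <- as.numeric(sub(".*t_smt=([-0-9.eE+]+).*", "\\1", cm))
    rows <- strsplit(trimws(lines[(i + 2):(i + 1 + n)]), "[[:space:]]+")
    if (any(lengths(rows) != 4))
      stop("format error: malformed atom line in frame starting at line ", i)
    mat <- matrix(as.numeric(unlist(lapply(rows, `[`, 2:4))), n, 3,
                  byrow = TRUE)
    labels <- vapply(rows, `[`, character(1), 1)
    frames[[length(frames) + 1]] <- mat
    steps <- c(steps, step)
    if (is.na(eff_dt) && step > 0) eff_dt <- tsmt / step
    i <- i + 2 + n
  }
  if (is.na(eff_dt)) eff_dt <- 1
  new_trajectory(frames, steps, dt = eff_dt, effective_dt = eff_dt,
                 labels = labels)
}

#' Write / read folding records as CSV
#'
#' Columns `sim_id, time_ns, event` with `event` coded 0/1.
#'
#' @param records a `folding_records` data frame.
#' @param path file path.
#' @return [write_folding_records()] returns `path` invisibly;
#'   [read_folding_records()] returns a `folding_records`.
#' @export
write_folding_records <- function(records, path) {
  write.csv(data.frame(sim_id = records$sim_id,
                       time_ns = records$time,
                       event = as.integer(records$event)),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_folding_records
#' @export
read_folding_records <- function(path) {
  d <- read.csv(path)
  need <- c("sim_id", "time_ns", "event")
  if (!all(need %in% names(d)))
    stop("records CSV must have columns sim_id, time_ns, event")
  folding_records(d$time_ns, d$event != 0, d$sim_id)
}

#' Write a population series as CSV (printed-table layout)
#'
#' @param series a `population_series`.
#' @param path file path.
#' @param digits percentages are rounded to this many decimals in the
#'   table-style output (default 0, matching printed tables); internal
#'   objects keep full precision.
#' @return `path`, invisibly.
#' @export
write_population_series <- function(series, path, digits = 0) {
  d <- as.data.frame(series)
  d$mean_pct <- round(d$mean_pct, digits)
  d$sd_pct <- round(d$sd_pct, digits)
  d$se_pct <- round(d$se_pct, digits)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write a toy system + force field + constraints as a JSON config
#'
#' @param system a `toy_system`.
#' @param ff a `force_field`.
#' @param path output file.
#' @param constraints optional `constraint_set`.
#' @return `path`, invisibly.
#' @export
write_system_json <- function(system, ff, path, constraints = NULL) {
  obj <- list(
    particles = data.frame(mass = system$masses,
                           x = system$positions[, 1],
                           y = system$positions[, 2],
                           z = system$positions[, 3],
                           vx = system$velocities[, 1],
                           vy = system$velocities[, 2],
                           vz = system$velocities[, 3],
                           label = system$labels,
                           residue = system$residue_ids),
    bonds = ff$bonds, angles = ff$angles, torsions = ff$torsions,
    lj = ff$lj)
  if (!is.null(constraints))
    obj$constraints <- list(pairs = constraints$pairs,
                            tolerance = constraints$tolerance,
                            max_iterations = constraints$max_iterations)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a toy system JSON config
#'
#' @param path file written by [write_system_json()].
#' @return list with `system`, `ff` and (possibly NULL) `constraints`.
#' @export
read_system_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- obj$particles
  sys <- toy_system(p$mass, cbind(p$x, p$y, p$z), cbind(p$vx, p$vy, p$vz),
                    labels = p$label, residue_ids = p$residue)
  ff <- force_field(bonds = null_if_empty(obj$bonds),
                    angles = null_if_empty(obj$angles),
                    torsions = null_if_empty(obj$torsions),
                    lj_pairs = null_if_empty(obj$lj))
  cons <- NULL
  if (!is.null(obj$constraints))
    cons <- constraint_set(obj$constraints$pairs,
                           obj$constraints$tolerance,
                           obj$constraints$max_iterations)
  list(system = sys, ff = ff, constraints = cons)
}

null_if_empty <- function(m) {
  if (is.null(m) || NROW(m) == 0) NULL else as.matrix(m)
}

#' Write a run manifest
#'
#' Records the configuration snapshot, seed, toolkit version, MD5 checksums
#' of input/output files and a timestamp, so that a toy run is documented
#' the way production simulations are.
#'
#' @param path manifest output path (JSON).
#' @param config named list of parameters for the run.
#' @param seed integer seed.
#' @param inputs,outputs character vectors of file paths to checksum.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(path, config, seed, inputs = character(0),
                           outputs = character(0)) {
  sums <- function(fs) {
    fs <- fs[file.exists(fs)]
    if (length(fs) == 0) return(NULL)
    as.list(setNames(unname(tools::md5sum(fs)), basename(fs)))
  }
  man <- list(toolkit = "lmdk",
              version = as.character(packageVersion("lmdk")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              seed = seed, config = config,
              input_checksums = sums(inputs),
              output_checksums = sums(outputs))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(man)
}
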