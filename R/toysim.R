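#' Construct a toy molecular system
#'
#' A `toy_system` bundles the particles the engine propagates: masses,
#' Cartesian positions and velocities, plus optional per-particle atom-name
#' labels (e.g. `"CA"`, `"CB"`) and 1-based residue identifiers so that a toy
#' chain can flow through the structure metrics unchanged.
#'
#' @param masses numeric vector of particle masses (amu), all `> 0`.
#' @param positions numeric `n x 3` matrix of coordinates (Angstrom).
#' @param velocities numeric `n x 3` matrix (Angstrom/fs); defaults to rest.
#' @param labels character vector of atom names (default `"X"`).
#' @param residue_ids integer vector of 1-based residue ids (default `1:n`).
#' @return An object of class `toy_system`.
#' @export
toy_system <- function(masses, positions, velocities = NULL, labels = NULL,
                       residue_ids = NULL) {
  positions <- as.matrix(positions)
  n <- length(masses)
  if (!is.numeric(masses) || any(!is.finite(masses)) || any(masses <= 0))
    stop("all masses must be finite and strictly positive")
  if (ncol(positions) != 3 || nrow(positions) != n)
    stop("positions must be an n x 3 matrix matching length(masses)")
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  velocities <- as.matrix(velocities)
  if (!identical(dim(velocities), dim(positions)))
    stop("positions and velocities must have identical shape")
  if (is.null(labels)) labels <- rep("X", n)
  if (is.null(residue_ids)) residue_ids <- seq_len(n)
  structure(
    list(masses = as.numeric(masses),
         positions = unname(positions * 1.0),
         velocities = unname(velocities * 1.0),
         labels = as.character(labels),
         residue_ids = as.integer(residue_ids)),
    class = "toy_system")
}

#' @export
print.toy_system <- function(x, ...) {
  cat(sprintf("<toy_system> %d particles, total mass %.4g amu\n",
              length(x$masses), sum(x$masses)))
  invisible(x)
}

#' Construct a force field for toy systems
#'
#' Functional forms: harmonic bonds `1/2 kb (r - r0)^2`, harmonic angles
#' `1/2 ka (theta - theta0)^2`, cosine torsions `vn/2 (1 + cos(n phi - phase))`
#' and 12-6 Lennard-Jones pairs `4 eps ((sigma/r)^12 - (sigma/r)^6)`.
#'
#' @param bonds matrix/data.frame with columns `i, j, k, r0`
#'   (kcal/mol/A^2, Angstrom); 1-based particle indices.
#' @param angles columns `i, j, k, ka, theta0` (kcal/mol/rad^2, rad); `j` is
#'   the vertex.
#' @param torsions columns `i, j, k, l, vn, n, phase` (kcal/mol, -, rad).
#' @param lj_pairs columns `i, j, eps, sigma` (kcal/mol, Angstrom).
#' @return An object of class `force_field`.
#' @export
force_field <- function(bonds = NULL, angles = NULL, torsions = NULL,
                        lj_pairs = NULL) {
  as_mat <- function(x, k, what) {
    if (is.null(x)) return(matrix(0, 0, k))
    x <- as.matrix(x)
    if (length(x) == k && nrow(x) == k) x <- matrix(x, 1, k)
    if (ncol(x) != k) stop(sprintf("%s must have %d columns", what, k))
    unname(x * 1.0)
  }
  ff <- list(bonds = as_mat(bonds, 4, "bonds"),
             angles = as_mat(angles, 5, "angles"),
             torsions = as_mat(torsions, 7, "torsions"),
             lj = as_mat(lj_pairs, 4, "lj_pairs"))
  if (nrow(ff$bonds) && any(ff$bonds[, 1] == ff$bonds[, 2]))
    stop("bond with i == j")
  if (nrow(ff$bonds) && any(ff$bonds[, 3] < 0)) stop("negative bond constant")
  if (nrow(ff$angles) && any(ff$angles[, 4] < 0))
    stop("negative angle constant")
  if (nrow(ff$lj) && any(ff$lj[, 3] < 0)) stop("negative LJ epsilon")
  class(ff) <- "force_field"
  ff
}

#' Construct a set of holonomic pair-distance (SHAKE) constraints
#'
#' @param pairs matrix/data.frame with columns `i, j, length` (1-based
#'   indices, target length in Angstrom).
#' @param tolerance relative distance tolerance (dimensionless, `> 0`).
#' @param max_iterations maximum SHAKE sweeps before declaring failure; a
#'   non-converging step signals a too-large time step and is raised as an
#'   error, never silently accepted.
#' @return An object of class `constraint_set`.
#' @export
constraint_set <- function(pairs, tolerance = 1e-8, max_iterations = 500L) {
  pairs <- as.matrix(pairs)
  if (length(pairs) == 3 && nrow(pairs) == 3) pairs <- matrix(pairs, 1, 3)
  if (ncol(pairs) != 3) stop("pairs must have columns (i, j, length)")
  if (tolerance <= 0) stop("tolerance must be > 0")
  if (any(pairs[, 3] <= 0)) stop("target lengths must be > 0")
  if (any(pairs[, 1] == pairs[, 2])) stop("constraint with i == j")
  structure(list(pairs = unname(pairs * 1.0), tolerance = tolerance,
                 max_iterations = as.integer(max_iterations)),
            class = "constraint_set")
}

#' Integrator configuration
#'
#' @param dt time step in fs (standard-mass time).
#' @param n_steps total number of integration steps.
#' @param save_interval steps between saved frames; frames are saved at steps
#'   `save_interval, 2*save_interval, ...` (the step-0 conformation is not a
#'   frame).
#' @param thermostat `NULL` for NVE, or `list(t_target = , tau_t = )` for
#'   Berendsen weak coupling (K, fs).
#' @param seed integer seed used to draw initial Maxwell-Boltzmann
#'   velocities when requested; recorded for reproducibility.
#' @return An object of class `integrator_config`.
#' @export
integrator_config <- function(dt, n_steps, save_interval,
                              thermostat = NULL, seed = 1L) {
  if (dt <= 0) stop("dt must be > 0")
  if (save_interval < 1 || n_steps < save_interval)
    stop("need n_steps >= save_interval >= 1")
  if (!is.null(thermostat)) {
    if (is.null(thermostat$t_target) || is.null(thermostat$tau_t))
      stop("thermostat needs t_target (K) and tau_t (fs)")
    if (thermostat$t_target <= 0 || thermostat$tau_t <= 0)
      stop("thermostat parameters must be positive")
  }
  structure(list(dt = dt, n_steps = as.integer(n_steps),
                 save_interval = as.integer(save_interval),
                 thermostat = thermostat, seed = as.integer(seed)),
            class = "integrator_config")
}

new_trajectory <- function(frames, step_indices, dt, effective_dt = dt,
                           potential = NULL, kinetic = NULL, labels = NULL) {
  structure(list(frames = frames, step_indices = as.integer(step_indices),
                 dt = dt, effective_dt = effective_dt,
                 potential = potential, kinetic = kinetic, labels = labels),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> %d frames of %d particles, dt = %g fs (effective %g fs)\n",
    length(x$frames), if (length(x$frames)) nrow(x$frames[[1]]) else 0L,
    x$dt, x$effective_dt))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Compute forces and potential energy
#'
#' Forces are the exact negative gradient of the total potential (harmonic
#' bonds and angles, cosine torsions, 12-6 Lennard-Jones).  For
#' translation-invariant potentials they sum to zero.
#'
#' @param system a `toy_system`.
#' @param ff a `force_field`.
#' @return `n x 3` matrix of forces (kcal/mol/A) with the potential energy
#'   (kcal/mol) attached as attribute `"potential"`.
#' @export
compute_forces <- function(system, ff) {
  res <- cpp_forces(system$positions, unclass(ff))
  structure(res$forces, potential = res$potential)
}

#' Total potential energy of a configuration
#' @inheritParams compute_forces
#' @return potential energy in kcal/mol.
#' @export
potential_energy <- function(system, ff) {
  cpp_forces(system$positions, unclass(ff))$potential
}

#' Kinetic energy of a system (kcal/mol)
#' @param system a `toy_system`.
#' @export
kinetic_energy <- function(system) {
  0.5 * sum(system$masses * rowSums(system$velocities^2)) / KCAL_CONV
}

#' Instantaneous temperature
#'
#' `T = 2 KE / (N_dof kB)` with `kB = 0.0019872` kcal/mol/K and
#' `N_dof = 3 n_particles - n_constraints`.
#'
#' @param system a `toy_system`.
#' @param n_constraints number of holonomic constraints applied.
#' @return temperature in K.
#' @export
instantaneous_temperature <- function(system, n_constraints = 0L) {
  ndof <- 3 * length(system$masses) - n_constraints
  2 * kinetic_energy(system) / (ndof * KB_KCAL)
}

#' Berendsen weak-coupling velocity scaling factor
#'
#' `sqrt(1 + (dt/tau_t) (t_target/t_inst - 1))`.
#'
#' @param t_inst instantaneous temperature (K), `> 0`.
#' @param t_target target temperature (K).
#' @param tau_t coupling time constant (fs).
#' @param dt time step (fs).
#' @return dimensionless velocity scaling factor.
#' @export
berendsen_scale_factor <- function(t_inst, t_target, tau_t, dt) {
  if (t_inst <= 0) stop("degenerate state: t_inst must be > 0")
  sqrt(1 + (dt / tau_t) * (t_target / t_inst - 1))
}

#' SHAKE constraint projection
#'
#' Projects `positions` onto the constraint manifold using mass-weighted
#' corrections along the reference bond vectors (the classic SHAKE
#' iteration).  Exceeding `max_iterations` is an error, mirroring the
#' integration failures seen when the time step is too large.
#'
#' @param positions `n x 3` matrix of post-drift coordinates (Angstrom).
#' @param reference_positions `n x 3` matrix of pre-drift coordinates.
#' @param constraints a `constraint_set`.
#' @param masses particle masses (amu).
#' @return corrected `n x 3` position matrix with attribute `"iterations"`.
#' @export
shake_project <- function(positions, reference_positions, constraints,
                          masses) {
  res <- cpp_shake(as.matrix(positions), as.matrix(reference_positions),
                   unclass(constraints), as.numeric(masses))
  structure(res$positions, iterations = res$iterations)
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Each velocity component of particle `i` is drawn from a normal
#' distribution with variance `kB T c / m_i` (c the unit conversion
#' constant), so that the expected kinetic energy per degree of freedom is
#' `kB T / 2`.
#'
#' @param system a `toy_system`.
#' @param t_target temperature in K.
#' @param seed integer seed.
#' @return the system with velocities replaced by the draw.
#' @export
maxwell_boltzmann_velocities <- function(system, t_target, seed = 1L) {
  set.seed(as.integer(seed))
  n <- length(system$masses)
  sd_i <- sqrt(KB_KCAL * t_target * KCAL_CONV / system$masses)
  system$velocities <- matrix(rnorm(3 * n), n, 3) * sd_i
  system
}

#' Advance a system by one velocity-Verlet step
#'
#' Half-kick, drift (with optional SHAKE projection and matching velocity
#' correction), force recompute, half-kick, then RATTLE velocity projection
#' along constraints.
#'
#' @param system a `toy_system`.
#' @param ff a `force_field`.
#' @param dt time step in fs.
#' @param constraints optional `constraint_set`.
#' @return the updated `toy_system`.
#' @export
velocity_verlet_step <- function(system, ff, dt, constraints = NULL) {
  if (dt <= 0) stop("dt must be > 0")
  res <- cpp_run(system$positions, system$velocities, system$masses,
                 unclass(ff),
                 if (is.null(constraints)) NULL else unclass(constraints),
                 dt, 1L, 1L, FALSE, 0, 1, FALSE)
  system$positions <- res$final_positions
  system$velocities <- res$final_velocities
  system
}

#' Run a toy MD simulation
#'
#' Propagates the system for `config$n_steps` velocity-Verlet steps, saving a
#' frame every `config$save_interval` steps (so exactly
#' `floor(n_steps/save_interval)` frames at steps `save_interval,
#' 2*save_interval, ...`).  With a thermostat configured, velocities are
#' rescaled each step by the Berendsen factor.  If `draw_velocities` is TRUE,
#' initial velocities are drawn from the Maxwell-Boltzmann distribution at
#' the thermostat target temperature using `config$seed`; the dynamics
#' themselves are deterministic, so equal (system, config, seed) gives
#' bitwise-identical trajectories.
#'
#' @param system a `toy_system`.
#' @param ff a `force_field`.
#' @param config an `integrator_config`.
#' @param constraints optional `constraint_set`.
#' @param draw_velocities draw Maxwell-Boltzmann initial velocities at the
#'   thermostat target temperature (requires a thermostat).
#' @param save_energies record per-frame potential and kinetic energy.
#' @param effective_dt effective (standard-mass equivalent) time step for the
#'   analysis time axis; defaults to `config$dt`.
#' @return a `trajectory`; the final state is attached as attribute
#'   `"final_system"` so runs can be continued.
#' @export
run_simulation <- function(system, ff, config, constraints = NULL,
                           draw_velocities = FALSE, save_energies = FALSE,
                           effective_dt = config$dt) {
  stopifnot(inherits(config, "integrator_config"))
  if (draw_velocities) {
    if (is.null(config$thermostat))
      stop("draw_velocities requires a thermostat target temperature")
    system <- maxwell_boltzmann_velocities(system,
                                           config$thermostat$t_target,
                                           config$seed)
  }
  th <- config$thermostat
  res <- cpp_run(system$positions, system$velocities, system$masses,
                 unclass(ff),
                 if (is.null(constraints)) NULL else unclass(constraints),
                 config$dt, config$n_steps, config$save_interval,
                 !is.null(th),
                 if (is.null(th)) 0 else th$t_target,
                 if (is.null(th)) 1 else th$tau_t,
                 save_energies)
  nf <- length(res$step_indices)
  np <- length(system$masses)
  frames <- lapply(seq_len(nf), function(k)
    matrix(res$frames[, , k, drop = FALSE], np, 3))
  final <- system
  final$positions <- res$final_positions
  final$velocities <- res$final_velocities
  traj <- new_trajectory(frames, res$step_indices, config$dt, effective_dt,
                         potential = res$potential, kinetic = res$kinetic,
                         labels = system$labels)
  attr(traj, "final_system") <- final
  traj
}
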