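#' Specification for a synthetic two-state folding simulation set
#'
#' Defines a continuous-time two-state Markov chain D <-> N with folding
#' rate `k_f` (D -> N) and unfolding rate `k_u` (N -> D), together with the
#' frame grid and the RMSD emission model used to mimic an analysed MD
#' trajectory: each saved frame emits an RMSD drawn uniformly from the
#' range of its current state.  The default emission ranges (native
#' U(1.0, 1.9) A, nonnative U(2.5, 8.0) A, cutoff 1.96 A) mimic folded
#' beta-hairpin conformations observed around 1.5 A while keeping the
#' classification unambiguous: the ranges must stay at least 0.05 A clear
#' of the cutoff on either side.
#'
#' @param k_f folding rate in 1/ns (>= 0).
#' @param k_u unfolding rate in 1/ns (>= 0); not both zero.
#' @param n_sims number of independent simulations.
#' @param n_steps steps per simulation.
#' @param save_interval steps between saved frames.
#' @param effective_dt effective time step in fs.
#' @param seed integer seed.
#' @param native_range,nonnative_range RMSD emission intervals (Angstrom).
#' @param cutoff native classification cutoff (Angstrom).
#' @return object of class `two_state_spec`.
#' @export
two_state_spec <- function(k_f, k_u = 0, n_sims = 20L, n_steps = 5e6,
                           save_interval = 1e3, effective_dt = 3.16,
                           seed = 1L,
                           native_range = c(1.0, 1.9),
                           nonnative_range = c(2.5, 8.0),
                           cutoff = 1.96) {
  if (k_f < 0 || k_u < 0 || (k_f == 0 && k_u == 0))
    stop("rates must be >= 0 and not both zero")
  if (max(native_range) > cutoff - 0.05)
    stop("spec error: native emission range must lie <= cutoff - 0.05 A")
  if (min(nonnative_range) < cutoff + 0.05)
    stop("spec error: nonnative emission range must lie >= cutoff + 0.05 A")
  structure(list(k_f = k_f, k_u = k_u, n_sims = as.integer(n_sims),
                 n_steps = n_steps, save_interval = save_interval,
                 effective_dt = effective_dt, seed = as.integer(seed),
                 native_range = native_range,
                 nonnative_range = nonnative_range, cutoff = cutoff),
            class = "two_state_spec")
}

#' Simulate two-state folding trajectories
#'
#' Each simulation starts in the nonnative state D; state waiting times are
#' drawn exponentially (rate `k_f` in D, `k_u` in N) and an RMSD is emitted
#' per saved frame from the current state's uniform range.  Both the
#' emitted series and the exact ground-truth first D -> N transition times
#' are returned, so estimator bias from frame discretisation is measurable
#' rather than hidden.
#'
#' @param spec a `two_state_spec`.
#' @return list with
#'   \item{rmsd}{frames x n_sims matrix of emitted RMSDs (Angstrom);}
#'   \item{frame_times_ns}{times of the saved frames (ns);}
#'   \item{truth}{`folding_records` of exact first-passage times, censored
#'     at the simulated length for runs that never fold;}
#'   \item{spec}{the input spec.}
#' @export
simulate_two_state <- function(spec) {
  stopifnot(inherits(spec, "two_state_spec"))
  set.seed(spec$seed)
  n_frames <- floor(spec$n_steps / spec$save_interval)
  frame_times <- seq_len(n_frames) * spec$save_interval *
    spec$effective_dt * 1e-6 # ns
  t_end <- spec$n_steps * spec$effective_dt * 1e-6
  rmsd <- matrix(NA_real_, n_frames, spec$n_sims)
  truth_time <- numeric(spec$n_sims)
  truth_event <- logical(spec$n_sims)
  for (s in seq_len(spec$n_sims)) {
    # event-driven pass over [0, t_end]
    t_now <- 0
    native <- FALSE
    first_fold <- NA_real_
    native_at <- rep(FALSE, n_frames)
    while (t_now < t_end) {
      rate <- if (native) spec$k_u else spec$k_f
      t_next <- if (rate > 0) t_now + rexp(1, rate) else t_end
      covered <- frame_times > t_now & frame_times <= min(t_next, t_end)
      native_at[covered] <- native
      if (!native && is.na(first_fold) && rate > 0 && t_next <= t_end)
        first_fold <- t_next
      native <- !native
      t_now <- t_next
    }
    truth_event[s] <- !is.na(first_fold)
    truth_time[s] <- if (truth_event[s]) first_fold else t_end
    nn <- sum(!native_at)
    rmsd[!native_at, s] <- runif(nn, spec$nonnative_range[1],
                                 spec$nonnative_range[2])
    rmsd[native_at, s] <- runif(n_frames - nn, spec$native_range[1],
                                spec$native_range[2])
  }
  list(rmsd = rmsd, frame_times_ns = frame_times,
       truth = folding_records(truth_time, truth_event),
       spec = spec)
}

#' Build a double-well bead-chain toy folder
#'
#' A four-bead chain with stiff harmonic bonds and angles and a
#' periodicity-2 torsion `barrier/2 (1 + cos 2 phi)`, giving two
#' equal-energy minima at dihedral angles of -90 deg ("folded") and
#' +90 deg ("extended") separated by `barrier` kcal/mol at phi = 0.  The
#' dihedral distance from the folded minimum is mapped linearly to a
#' pseudo-RMSD in Angstrom ([double_well_rc()]) so the chain feeds the
#' native-state classification and kinetics pipeline unchanged: the folded
#' minimum sits at 0 A and the extended minimum at `separation` A.
#'
#' @param barrier barrier height in kcal/mol (> 0).
#' @param separation pseudo-RMSD distance between the two minima
#'   (Angstrom).
#' @param mass bead mass in amu.
#' @param extended start the chain at the extended minimum (default) or the
#'   folded one.
#' @return list with `system` (a `toy_system`), `ff` (a `force_field`),
#'   `separation`, `barrier`, and the dihedral indices `dihedral`.
#' @export
build_double_well <- function(barrier, separation = 8, mass = 12,
                              extended = TRUE) {
  if (barrier <= 0) stop("barrier must be > 0")
  b0 <- 1.53
  th0 <- 111 * pi / 180
  phi0 <- if (extended) pi / 2 else -pi / 2
  pos <- chain_coords(b0, th0, phi0)
  sys <- toy_system(rep(mass, 4), pos,
                    labels = c("C1", "C2", "C3", "C4"),
                    residue_ids = 1:4)
  ff <- force_field(
    bonds = rbind(c(1, 2, 600, b0), c(2, 3, 600, b0), c(3, 4, 600, b0)),
    angles = rbind(c(1, 2, 3, 120, th0), c(2, 3, 4, 120, th0)),
    torsions = rbind(c(1, 2, 3, 4, barrier, 2, 0)))
  list(system = sys, ff = ff, separation = separation, barrier = barrier,
       dihedral = c(1L, 2L, 3L, 4L))
}

# place a 4-bead chain with given bond length, angle and dihedral
chain_coords <- function(b0, th0, phi) {
  p1 <- c(0, 0, 0)
  p2 <- c(b0, 0, 0)
  p3 <- p2 + b0 * c(-cos(th0), sin(th0), 0)
  # standard internal-coordinate placement of atom 4
  bc <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  n <- c(0, 0, 1) # normal of the 1-2-3 plane
  m <- pracma_cross(n, bc)
  d <- b0 * (-cos(th0) * bc + sin(th0) * (cos(phi) * m + sin(phi) * n))
  rbind(p1, p2, p3, p3 + d)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Dihedral angle of four points
#'
#' Signed dihedral in radians, in (-pi, pi].
#'
#' @param positions `n x 3` coordinate matrix.
#' @param idx four atom indices.
#' @return dihedral angle in radians.
#' @export
dihedral_angle <- function(positions, idx = 1:4) {
  p <- positions[idx, , drop = FALSE]
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  m <- pracma_cross(b1, b2)
  n <- pracma_cross(b2, b3)
  atan2(sum(pracma_cross(m, n) * b2 / sqrt(sum(b2^2))), sum(m * n))
}

#' Pseudo-RMSD reaction coordinate of a double-well chain
#'
#' Maps the (wrapped) dihedral distance from the folded minimum at -90 deg
#' linearly to Angstrom: 0 at the folded minimum, `separation` at the
#' extended one.
#'
#' @param x a `trajectory`, a list of frames, or a single `n x 3` position
#'   matrix.
#' @param separation pseudo-RMSD distance between the minima (Angstrom).
#' @param dihedral four atom indices.
#' @return numeric pseudo-RMSD value(s) in Angstrom.
#' @export
double_well_rc <- function(x, separation = 8, dihedral = 1:4) {
  frames <- if (inherits(x, "trajectory")) x$frames
            else if (is.matrix(x)) list(x) else x
  phi_fold <- -pi / 2
  vapply(frames, function(fr) {
    d <- dihedral_angle(fr, dihedral) - phi_fold
    d <- atan2(sin(d), cos(d)) # wrap to (-pi, pi]
    abs(d) * separation / pi
  }, numeric(1))
}

#' Potential energy of a double-well chain at a given dihedral
#'
#' Evaluates the chain potential with bonds and angles at equilibrium and
#' the dihedral set to `phi`; used to check the two-minimum construction.
#'
#' @param dw result of [build_double_well()].
#' @param phi dihedral angle(s) in radians.
#' @return potential energy (kcal/mol) at each `phi`.
#' @export
double_well_potential <- function(dw, phi) {
  vapply(phi, function(p) {
    pos <- chain_coords(1.53, 111 * pi / 180, p)
    sys <- toy_system(dw$system$masses, pos)
    potential_energy(sys, dw$ff)
  }, numeric(1))
}

#' First barrier-crossing step of a thermostatted double-well run
#'
#' Runs the chain from the extended minimum with Maxwell-Boltzmann initial
#' velocities and a Berendsen thermostat, and reports the step index of the
#' first saved frame whose pseudo-RMSD is at or below `cutoff` (NA if no
#' crossing).  `lambda` applies uniform mass scaling before the run, so the
#' sampling gain of the low-mass regime at equal time step is directly
#' measurable.
#'
#' @param dw result of [build_double_well()].
#' @param t_target thermostat temperature (K).
#' @param lambda mass scaling factor.
#' @param dt time step (fs).
#' @param n_steps steps to run.
#' @param save_interval frame spacing in steps.
#' @param tau_t thermostat coupling time (fs).
#' @param cutoff pseudo-RMSD cutoff (Angstrom).
#' @param seed seed for the velocity draw(s).
#' @param reassign_interval if set, redraw all velocities from the
#'   Maxwell-Boltzmann distribution every this many steps.  A weak-coupling
#'   thermostat alone is not ergodic on a four-bead chain (the torsional
#'   mode decouples and barrier crossings stop after the initial
#'   transient); periodic velocity reassignment (Andersen-style massive
#'   collisions) restores thermally activated crossings.
#' @return first-crossing step count (`NA` if never crossed).
#' @export
double_well_first_crossing <- function(dw, t_target, lambda = 1, dt = 1,
                                       n_steps = 2e5, save_interval = 100,
                                       tau_t = 100, cutoff = 1.96,
                                       seed = 1L,
                                       reassign_interval = NULL) {
  sys <- scale_masses(dw$system, lambda)
  chunk <- if (is.null(reassign_interval)) n_steps
           else as.integer(reassign_interval)
  done <- 0; k <- 0
  while (done < n_steps) {
    k <- k + 1
    cfg <- integrator_config(dt, min(chunk, n_steps - done), save_interval,
                             thermostat = list(t_target = t_target,
                                               tau_t = tau_t),
                             seed = as.integer((as.numeric(seed) * 100000 +
                                                  k) %% 2147483647))
    traj <- run_simulation(sys, dw$ff, cfg, draw_velocities = TRUE)
    rc <- double_well_rc(traj, dw$separation, dw$dihedral)
    hit <- which(rc <= cutoff)
    if (length(hit)) return(done + as.numeric(traj$step_indices[hit[1]]))
    sys <- attr(traj, "final_system")
    done <- done + cfg$n_steps
  }
  NA_real_
}
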