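# Shared fixture builders (all generated in code).

# Argon-like Lennard-Jones cluster near a cubic lattice, with small seeded
# velocities; gentle enough that 1000-step runs stay quasi-harmonic.
lj_cluster <- function(n = 10, seed = 1, vel_sd = 2e-4) {
  set.seed(seed)
  g <- as.matrix(expand.grid(0:1, 0:1, 0:2))[seq_len(n), ] * 3.8
  pos <- g + matrix(rnorm(n * 3, sd = 0.05), n, 3)
  vel <- matrix(rnorm(n * 3, sd = vel_sd), n, 3)
  pairs <- t(combn(n, 2))
  list(system = toy_system(rep(39.948, n), pos, vel),
       ff = force_field(lj_pairs = cbind(pairs, 0.238, 3.4)))
}

# One light particle bonded to a quasi-fixed heavy anchor: an effectively
# one-dimensional harmonic oscillator with spring constant k and mass m.
anchored_oscillator <- function(k = 100, m = 12, r0 = 1.5, displace = 0.2) {
  list(system = toy_system(c(1e10, m),
                           rbind(c(0, 0, 0), c(r0 + displace, 0, 0))),
       ff = force_field(bonds = c(1, 2, k, r0)))
}

# Random bonded/LJ system exercising every force-field term.
random_system <- function(seed, n = 5) {
  set.seed(seed)
  list(system = toy_system(runif(n, 1, 20), matrix(rnorm(n * 3, sd = 2), n, 3)),
       ff = force_field(
         bonds = rbind(c(1, 2, 300, 1.5), c(2, 3, 250, 1.4)),
         angles = rbind(c(1, 2, 3, 80, 1.9)),
         torsions = rbind(c(1, 2, 3, 4, 2.5, 3, 0.4),
                          c(2, 3, 4, 5, 1.0, 2, 0)),
         lj_pairs = rbind(c(1, 5, 0.3, 3.2), c(1, 4, 0.2, 2.9))))
}

# Central finite-difference gradient of the potential (independent oracle
# for compute_forces).
fd_forces <- function(system, ff, h = 1e-5) {
  n <- length(system$masses)
  fd <- matrix(0, n, 3)
  for (i in seq_len(n)) for (d in 1:3) {
    pp <- system$positions; pp[i, d] <- pp[i, d] + h
    pm <- system$positions; pm[i, d] <- pm[i, d] - h
    fd[i, d] <- -(potential_energy(toy_system(system$masses, pp), ff) -
                    potential_energy(toy_system(system$masses, pm), ff)) /
      (2 * h)
  }
  fd
}

# Simple 2-residue model structure (CA/CB + a CA-only glycine-like residue).
model_structure <- function(coords_shift = c(0, 0, 0)) {
  xyz <- rbind(c(0, 0, 0), c(1.5, 0.4, 0.2), c(3.8, 0.1, -0.3),
               c(5.1, 1.2, 0.4), c(6.0, -0.8, 1.1))
  structure_model(c("CA", "CB", "CA", "CA", "CB"),
                  c(1L, 1L, 2L, 3L, 3L),
                  sweep(xyz, 2, coords_shift, "+"))
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_r <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_r)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}
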