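test_that("forces are the negative potential gradient", {
  # two bonded particles at exactly r0: minimum of the harmonic term
  sys <- toy_system(c(12, 12), rbind(c(0, 0, 0), c(1.5, 0, 0)))
  ff <- force_field(bonds = c(1, 2, 300, 1.5))
  expect_equal(max(abs(compute_forces(sys, ff))), 0)

  # LJ pair at r = sigma: |F| = 24 eps / sigma along the axis
  sig <- 3.2
  s2 <- toy_system(c(1, 1), rbind(c(0, 0, 0), c(sig, 0, 0)))
  f2 <- compute_forces(s2, force_field(lj_pairs = c(1, 2, 1, sig)))
  expect_equal(f2[1, 1], -24 / sig, tolerance = 1e-12)
  expect_equal(f2[2, 1], 24 / sig, tolerance = 1e-12)
  expect_equal(f2[, 2:3], matrix(0, 2, 2))

  # random systems: agree with the finite-difference oracle, net force zero
  for (seed in 1:3) {
    rs <- random_system(seed)
    F <- compute_forces(rs$system, rs$ff)
    expect_lt(max(abs(F - fd_forces(rs$system, rs$ff))) / max(abs(F)), 1e-6)
    expect_lt(max(abs(colSums(F))), 1e-9)
  }
})

test_that("force field and system constructors validate their invariants", {
  expect_error(toy_system(c(1, -1), matrix(0, 2, 3)), "positive")
  expect_error(toy_system(1, matrix(0, 2, 3)), "n x 3")
  expect_error(force_field(bonds = c(1, 1, 10, 1)), "i == j")
  expect_error(force_field(lj_pairs = c(1, 2, -0.1, 3)), "epsilon")
  expect_error(
    compute_forces(toy_system(1, matrix(0, 1, 3)),
                   force_field(bonds = c(1, 5, 10, 1))),
    "out of range")
  expect_error(constraint_set(c(1, 2, 1), tolerance = 0), "tolerance")
  expect_error(integrator_config(0, 10, 1), "dt")
})

test_that("velocity Verlet free flight and harmonic motion are exact", {
  # zero-force free particle advances by v*dt
  sys <- toy_system(c(1, 1), rbind(c(0, 0, 0), c(50, 0, 0)),
                    rbind(c(0.01, 0, 0), c(0, 0, 0)))
  ff <- force_field(lj_pairs = c(1, 2, 1e-12, 1))
  out <- velocity_verlet_step(sys, ff, 1)
  expect_equal(out$positions[1, ], c(0.01, 0, 0), tolerance = 1e-12)

  # oscillator period matches 2*pi*sqrt(m/(k c)) within 0.5% at dt = 0.1
  osc <- anchored_oscillator(k = 100, m = 12)
  tr <- run_simulation(osc$system, osc$ff, integrator_config(0.1, 5000, 1))
  x <- vapply(tr$frames, function(f) f[2, 1], numeric(1))
  crossings <- which(diff(sign(x - 1.5)) != 0)
  period <- 2 * mean(diff(crossings)) * 0.1
  expect_equal(period, 2 * pi * sqrt(12 / (100 * 4.184e-4)),
               tolerance = 0.005)

  # energy drift < 0.1% of initial PE over 1e4 steps at dt = 0.5
  tr2 <- run_simulation(osc$system, osc$ff,
                        integrator_config(0.5, 1e4, 10),
                        save_energies = TRUE)
  E <- tr2$potential + tr2$kinetic
  pe0 <- potential_energy(osc$system, osc$ff)
  expect_lt(max(abs(E - E[1])), 0.001 * pe0)
})

test_that("SHAKE projects onto the constraint manifold", {
  # fixed point: already satisfied constraints are returned unchanged
  pos <- rbind(c(0, 0, 0), c(1, 0, 0))
  cons <- constraint_set(c(1, 2, 1))
  out <- shake_project(pos, pos, cons, c(12, 1))
  expect_equal(out[, ], pos, ignore_attr = TRUE)

  # single pair stretched to 1.2x target: exact solve
  stretched <- rbind(c(0, 0, 0), c(1.2, 0, 0))
  out1 <- shake_project(stretched, stretched, cons, c(12, 1))
  expect_equal(sqrt(sum((out1[1, ] - out1[2, ])^2)), 1, tolerance = 1e-8)

  # triatomic, 3 coupled constraints, 5% perturbation: matches an
  # independent Newton solve for the mass-weighted projection multipliers
  ref <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  pairs <- rbind(c(1, 2, 1), c(2, 3, 1), c(1, 3, 1))
  cons3 <- constraint_set(pairs)
  m <- c(12, 1, 16)
  set.seed(3)
  pert <- ref + matrix(runif(9, -0.05, 0.05), 3, 3)
  out3 <- shake_project(pert, ref, cons3, m)
  d3 <- as.numeric(dist(out3))
  expect_true(all(abs(d3 - 1) <= 1e-8))

  xg <- function(g) {
    x <- pert
    for (k in 1:3) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      s <- ref[i, ] - ref[j, ]
      x[i, ] <- x[i, ] - g[k] * s / m[i]
      x[j, ] <- x[j, ] + g[k] * s / m[j]
    }
    x
  }
  resid <- function(g) {
    x <- xg(g)
    vapply(1:3, function(k)
      sum((x[pairs[k, 1], ] - x[pairs[k, 2], ])^2) - pairs[k, 3]^2,
      numeric(1))
  }
  g <- c(0, 0, 0)
  for (it in 1:100) {
    r <- resid(g)
    if (max(abs(r)) < 1e-15) break
    J <- vapply(1:3, function(k) {
      e <- numeric(3); e[k] <- 1e-8
      (resid(g + e) - r) / 1e-8
    }, numeric(3))
    g <- g - solve(J, r)
  }
  expect_lt(max(abs(xg(g) - out3)), 1e-6)

  # non-convergence is an error carrying the iteration limit
  tight <- constraint_set(c(1, 2, 1), tolerance = 1e-14,
                          max_iterations = 1L)
  expect_error(shake_project(stretched, stretched, tight, c(12, 1)),
               "converge")
})

test_that("Berendsen scaling factor follows the weak-coupling formula", {
  expect_identical(berendsen_scale_factor(300, 300, 100, 1), 1)
  expect_equal(berendsen_scale_factor(200, 300, 2, 2), sqrt(1.5))
  expect_error(berendsen_scale_factor(0, 300, 100, 1), "degenerate")

  # a thermostatted bonded chain holds its target temperature within 5%
  nb <- 8
  sys <- toy_system(rep(12, nb),
                    cbind(seq(0, by = 1.5, length.out = nb), 0, 0))
  ff <- force_field(bonds = cbind(1:(nb - 1), 2:nb, 200, 1.5))
  cfg <- integrator_config(1, 1e5, 100,
                           thermostat = list(t_target = 300, tau_t = 200),
                           seed = 5)
  tr <- run_simulation(sys, ff, cfg, draw_velocities = TRUE,
                       save_energies = TRUE)
  t_inst <- tr$kinetic * 2 / (3 * nb * 0.0019872)
  expect_equal(mean(t_inst[200:1000]), 300, tolerance = 0.05)
})

test_that("run_simulation saves frames on the configured grid, deterministically", {
  cl <- lj_cluster()
  cfg <- integrator_config(1, 1000, 100, seed = 42)
  tr <- run_simulation(cl$system, cl$ff, cfg)
  expect_identical(tr$step_indices, as.integer(seq(100, 1000, 100)))
  expect_identical(n_frames(tr), 10L)

  # bitwise determinism for equal (system, config, seed), thermostat on
  cfg_t <- integrator_config(1, 2000, 200,
                             thermostat = list(t_target = 50, tau_t = 500),
                             seed = 7)
  t1 <- run_simulation(cl$system, cl$ff, cfg_t, draw_velocities = TRUE)
  t2 <- run_simulation(cl$system, cl$ff, cfg_t, draw_velocities = TRUE)
  expect_identical(t1$frames, t2$frames)

  # NVE conservation on the LJ cluster: < 1% of |E0| over 1e5 steps
  tr_e <- run_simulation(cl$system, cl$ff,
                         integrator_config(1, 1e5, 1000),
                         save_energies = TRUE)
  E <- tr_e$potential + tr_e$kinetic
  E0 <- potential_energy(cl$system, cl$ff) + kinetic_energy(cl$system)
  expect_lt(max(abs(E - E0)), 0.01 * abs(E0))
})

test_that("momentum is conserved and SHAKE holds along full trajectories", {
  cl <- lj_cluster(seed = 4)
  tr <- run_simulation(cl$system, cl$ff, integrator_config(1, 1e4, 1e4))
  fin <- attr(tr, "final_system")
  p0 <- colSums(cl$system$masses * cl$system$velocities)
  p1 <- colSums(fin$masses * fin$velocities)
  scale <- sum(abs(cl$system$masses * cl$system$velocities))
  expect_lt(max(abs(p1 - p0)) / scale, 1e-10)

  # constrained dynamics: every saved frame satisfies all constraints
  set.seed(11)
  sys <- toy_system(c(12, 1, 1),
                    rbind(c(0, 0, 0), c(1.09, 0, 0), c(-0.4, 1.0, 0)),
                    matrix(rnorm(9, sd = 1e-3), 3, 3))
  ff <- force_field(angles = c(2, 1, 3, 35, 1.911),
                    lj_pairs = c(2, 3, 0.01, 1.7))
  cons <- constraint_set(rbind(c(1, 2, 1.09), c(1, 3, 1.09)))
  tr_c <- run_simulation(sys, ff, integrator_config(1, 5000, 50),
                         constraints = cons)
  viol <- vapply(tr_c$frames, function(fr) {
    max(abs(c(sqrt(sum((fr[1, ] - fr[2, ])^2)),
              sqrt(sum((fr[1, ] - fr[3, ])^2))) - 1.09)) / 1.09
  }, numeric(1))
  expect_true(all(viol <= 1e-8))
})
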