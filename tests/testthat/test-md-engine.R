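cfg0 <- sim_config(cutoff = 2.0)

test_that("Coulomb pair energy matches the closed form", {
  sys <- charge_pair(1, -1, 1.0)
  fr <- compute_forces(sys, sim_config(cutoff = 40, n_steps = 1))
  expect_equal(unname(fr$components["coulomb"]), -138.935458,
               tolerance = 1e-9)
  expect_equal(fr$potential_energy, sum(fr$components), tolerance = 1e-8)
})

test_that("harmonic bond at equilibrium has zero energy and force", {
  sys <- particle_system(rbind(c(1, 1, 1), c(1, 1, 1.1)), masses = c(1, 1),
                         box_edge = 10,
                         bonds = data.frame(i = 1, j = 2, kb = 1000, r0 = 0.1))
  fr <- compute_forces(sys, cfg0)
  expect_equal(unname(fr$components["bond"]), 0)
  expect_lt(max(abs(fr$forces)), 1e-10)
})

test_that("LJ closed forms at sigma and the minimum", {
  fr <- compute_forces(lj_pair(0.3), sim_config(cutoff = 40))
  expect_equal(unname(fr$components["lj"]), 0, tolerance = 1e-10)
  fr2 <- compute_forces(lj_pair(2^(1 / 6) * 0.3), sim_config(cutoff = 40))
  expect_equal(unname(fr2$components["lj"]), -1, tolerance = 1e-10)
})

test_that("overlapping atoms in a pair term raise a singularity error", {
  sys <- charge_pair(1, 1, 1e-9)
  expect_error(compute_forces(sys, cfg0), "singularity")
})

test_that("engine nonbonded energies match an independent brute force", {
  for (seed in c(1, 2, 3)) {
    sys <- random_system(n = 20, seed = seed)
    fr <- compute_forces(sys, sim_config(cutoff = 1.2))
    bf <- brute_force_nonbonded(sys, 1.2)
    expect_equal(unname(fr$components["lj"]), unname(bf["lj"]),
                 tolerance = 1e-12)
    expect_equal(unname(fr$components["coulomb"]), unname(bf["coulomb"]),
                 tolerance = 1e-12)
  }
})

test_that("forces are the negative numerical gradient of the potential", {
  sys <- random_system(n = 12, seed = 11)
  cfg <- sim_config(cutoff = 1.2)
  fr <- compute_forces(sys, cfg)
  h <- 1e-6
  for (i in c(1, 5, 9)) for (k in 1:3) {
    sp <- sys; sp$positions[i, k] <- sp$positions[i, k] + h
    sm <- sys; sm$positions[i, k] <- sm$positions[i, k] - h
    num <- -(compute_forces(sp, cfg)$potential_energy -
               compute_forces(sm, cfg)$potential_energy) / (2 * h)
    expect_equal(fr$forces[i, k], num,
                 tolerance = 1e-5 * max(1, abs(num)))
  }
})

test_that("field force follows F = q E(t) and vanishes for neutral atoms", {
  sys <- particle_system(rbind(c(1, 1, 1), c(2, 2, 2)), masses = c(1, 1),
                         box_edge = 8, charges = c(1, 0))
  f <- field_spec(0.5, 34.5)
  ff <- field_force(sys, f, t = 0)
  expect_equal(ff[1, ], c(0, 0, 48.24265), tolerance = 1e-5)
  expect_equal(ff[2, ], c(0, 0, 0))
  # zero-crossing of the cosine
  expect_equal(max(abs(field_force(sys, f, t = 1 / (4 * 34.5)))), 0,
               tolerance = 1e-9)
  expect_equal(max(abs(field_force(sys, field_spec(0, 34.5), 0))), 0)
})

test_that("a free particle drifts ballistically", {
  sys <- particle_system(matrix(c(1, 1, 1), 1), masses = 1, box_edge = 100,
                         velocities = matrix(c(1, 0, 0), 1))
  tr <- integrate_md(sys, sim_config(timestep = 1e-3, n_steps = 1000,
                                     sample_every = 1000))
  expect_equal(final_state(tr)$positions[1, ], c(2, 1, 1), tolerance = 1e-9)
})

test_that("a 1 ps-period oscillator returns to its start after one period", {
  # anchored particle, k = 4 pi^2 -> period exactly 1 ps for m = 1 u
  sys <- particle_system(rbind(c(5, 5, 5), c(5, 5, 5.1)),
                         masses = c(1e12, 1), box_edge = 10,
                         bonds = data.frame(i = 1, j = 2, kb = 4 * pi^2,
                                            r0 = 0))
  tr <- integrate_md(sys, sim_config(timestep = 1e-3, n_steps = 1000,
                                     sample_every = 1000))
  expect_equal(final_state(tr)$positions[2, 3], 5.1, tolerance = 1e-4)
})

test_that("total momentum is conserved without field or thermostat", {
  sys <- random_system(n = 15, seed = 4)
  sys$velocities <- matrix(rnorm(45, sd = 0.3), ncol = 3)
  tr <- integrate_md(sys, sim_config(timestep = 5e-4, n_steps = 2000,
                                     cutoff = 1.2, sample_every = 2000))
  p0 <- colSums(sys$masses * sys$velocities)
  p1 <- colSums(sys$masses * final_state(tr)$velocities)
  expect_lt(max(abs(p1 - p0)), 1e-10)
})

test_that("identical seeds give bitwise-identical Langevin trajectories", {
  sys <- thermalize(random_system(n = 10, seed = 5), 300, seed = 9)
  cfg <- sim_config(timestep = 5e-4, n_steps = 500, thermostat = "langevin",
                    friction = 1, seed = 77, cutoff = 1.2, sample_every = 50)
  t1 <- integrate_md(sys, cfg)
  t2 <- integrate_md(sys, cfg)
  expect_identical(t1$positions, t2$positions)
  expect_identical(t1$velocities, t2$velocities)
})

test_that("Langevin thermostat reaches the target temperature", {
  # 100-atom LJ gas at 300 K
  set.seed(1)
  pos <- expand.grid(x = 1:5, y = 1:5, z = 1:4)[, 1:3] * 0.8
  sys <- particle_system(as.matrix(pos), masses = rep(10, 100), box_edge = 6,
                         lj_sigma = rep(0.3, 100), lj_eps = rep(0.5, 100))
  sys <- thermalize(sys, 300, seed = 2)
  tr <- integrate_md(sys, sim_config(timestep = 2e-3, n_steps = 10000,
                                     thermostat = "langevin", friction = 1,
                                     temperature = 300, seed = 3,
                                     cutoff = 1.5, sample_every = 20))
  ke <- attr(tr, "kinetic")
  n2 <- length(ke)
  t_mean <- mean(2 * ke[(n2 %/% 2):n2] / (3 * 100 * md_constants$kB))
  expect_gt(t_mean, 270)
  expect_lt(t_mean, 330)
})

test_that("non-finite coordinates abort the run with the step number", {
  sys <- particle_system(matrix(c(1, 1, 1), 1), masses = 1, box_edge = 10,
                         velocities = matrix(c(1e307, 0, 0), 1))
  expect_error(integrate_md(sys, sim_config(timestep = 10, n_steps = 100,
                                            sample_every = 1)),
               "divergence")
})

test_that("ewald electrostatics is explicitly unavailable", {
  expect_error(sim_config(electrostatics = "ewald"), "not available")
})
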