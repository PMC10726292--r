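test_that("single receptor-ligand pair reproduces Coulomb and LJ closed forms", {
  sys <- particle_system(rbind(c(5, 5, 5), c(5, 5, 6)), masses = c(1, 1),
                         box_edge = 100, charges = c(1, -1),
                         groups = list(receptor = 1L, ligand = 2L))
  e <- mm_interaction_energy(sys, "receptor", "ligand")
  expect_equal(unname(e["E_elec"]), -138.935458, tolerance = 1e-9)
  expect_equal(unname(e["E_vdw"]), 0)

  sys2 <- lj_pair(2^(1 / 6) * 0.3, eps = 1)
  sys2$groups <- list(receptor = 1L, ligand = 2L)
  e2 <- mm_interaction_energy(sys2, "receptor", "ligand")
  expect_equal(unname(e2["E_vdw"]), -1, tolerance = 1e-10)
  expect_equal(unname(e2["E_elec"]), 0)
})

test_that("empty ligand group gives zero interaction", {
  sys <- charge_pair(1, -1, 1)
  e <- mm_interaction_energy(sys, 1:2, integer(0))
  expect_equal(unname(e), c(0, 0))
  expect_error(mm_interaction_energy(sys, 1:2, 2), "disjoint")
})

test_that("PB solver reproduces the Born ion within tolerance", {
  born <- -138.935458 / (2 * 0.2) * (1 - 1 / 80)
  sys <- particle_system(matrix(c(1, 1, 1), 1), masses = 1, box_edge = 2,
                         charges = 1, radii = 0.2)
  r <- polar_solvation(sys, grid_spacing = 0.05, eps_solute = 1,
                       eps_solvent = 80)
  expect_equal(r$energy, born, tolerance = 0.02)
})

test_that("PB energy vanishes without dielectric contrast and scales as q^2", {
  sys <- particle_system(matrix(c(1, 1, 1), 1), masses = 1, box_edge = 2,
                         charges = 1, radii = 0.2)
  r0 <- polar_solvation(sys, grid_spacing = 0.05, eps_solute = 80,
                        eps_solvent = 80)
  expect_equal(r0$energy, 0, tolerance = 1e-6)
  r1 <- polar_solvation(sys, grid_spacing = 0.05, eps_solute = 1,
                        eps_solvent = 80)
  sys$charges <- 2
  r2 <- polar_solvation(sys, grid_spacing = 0.05, eps_solute = 1,
                        eps_solvent = 80)
  expect_equal(r2$energy / r1$energy, 4, tolerance = 0.01)
})

test_that("coarse PB grids warn and zero radii error", {
  sys <- particle_system(matrix(c(1, 1, 1), 1), masses = 1, box_edge = 2,
                         charges = 1, radii = 0.2)
  expect_warning(polar_solvation(sys, grid_spacing = 0.15), "coarse")
  sys$radii <- 0
  expect_error(polar_solvation(sys), "positive radii")
})

test_that("Shrake-Rupley recovers the isolated-sphere area", {
  sa <- shrake_rupley(matrix(c(1, 1, 1), 1), radii = 0.2)
  expect_equal(sa, 4 * pi * 0.34^2, tolerance = 0.01)
})

test_that("nearly coincident spheres expose one sphere's worth of area", {
  sa <- shrake_rupley(rbind(c(1, 1, 1), c(1, 1, 1.001)), radii = c(0.2, 0.2))
  expect_equal(sum(sa), 4 * pi * 0.34^2, tolerance = 0.02)
})

test_that("nonpolar solvation is gamma * SASA + b", {
  sys <- particle_system(matrix(c(1, 1, 1), 1), masses = 1, box_edge = 5,
                         radii = 0.2)
  np <- nonpolar_solvation(sys, gamma = 2.27, b = 0.5)
  expect_equal(np$energy, 2.27 * np$sasa + 0.5)
  np0 <- nonpolar_solvation(sys, gamma = 0, b = 0)
  expect_equal(np0$energy, 0)
})

test_that("MM-only binding mean equals a direct per-frame pair sum", {
  set.seed(21)
  n <- 8
  topo <- particle_system(matrix(runif(3 * n, 4, 6), ncol = 3),
                          masses = rep(1, n), box_edge = 100,
                          charges = round(runif(n, -0.5, 0.5), 2),
                          lj_sigma = rep(0.25, n),
                          lj_eps = runif(n, 0.1, 0.5),
                          groups = list(receptor = 1:5, ligand = 6:8))
  nf <- 6
  pos <- array(runif(nf * n * 3, 4, 6), c(nf, n, 3))
  tr <- trajectory(topo, seq_len(nf) * 0.5, pos, array(0, c(nf, n, 3)))
  bb <- binding_free_energy(tr, "receptor", "ligand", 0.5,
                            n_boot = 50, solvation = FALSE)
  # oracle: direct double loop over receptor-ligand pairs per frame
  oracle <- mean(sapply(seq_len(nf), function(f) {
    s <- thzbind:::system_at_frame(tr, f)
    tot <- 0
    for (i in 1:5) for (j in 6:8) {
      r <- sqrt(sum((s$positions[i, ] - s$positions[j, ])^2))
      sij <- 0.25; eij <- sqrt(s$lj_eps[i] * s$lj_eps[j])
      tot <- tot + 138.935458 * s$charges[i] * s$charges[j] / r +
        4 * eij * ((sij / r)^12 - (sij / r)^6)
    }
    tot
  }))
  expect_equal(bb$G_binding, oracle, tolerance = 1e-8)
})

test_that("identical frames give the single-frame value with zero SE", {
  topo <- charge_pair(1, -1, 1)
  topo$groups <- list(receptor = 1L, ligand = 2L)
  pos <- array(0, c(3, 2, 3))
  for (f in 1:3) pos[f, , ] <- topo$positions
  tr <- trajectory(topo, c(0, 0.5, 1), pos, array(0, c(3, 2, 3)))
  bb <- binding_free_energy(tr, "receptor", "ligand", 0.5, n_boot = 100,
                            solvation = FALSE)
  expect_equal(bb$E_elec, -138.935458, tolerance = 1e-9)
  expect_equal(unname(bb$se_bootstrap["G_binding"]), 0)
  expect_equal(bb$G_binding,
               bb$E_vdw + bb$E_elec + bb$G_polar + bb$G_nonpolar,
               tolerance = 1e-9)
})

test_that("a two-frame toy averages exactly", {
  topo <- charge_pair(1, -1, 1)
  topo$groups <- list(receptor = 1L, ligand = 2L)
  pos <- array(0, c(2, 2, 3))
  pos[1, , ] <- topo$positions
  pos[2, , ] <- topo$positions; pos[2, 2, 3] <- pos[2, 2, 3] + 1  # r = 2
  tr <- trajectory(topo, c(0, 0.5), pos, array(0, c(2, 2, 3)))
  bb <- binding_free_energy(tr, "receptor", "ligand", 0.5, n_boot = 10,
                            solvation = FALSE)
  expect_equal(bb$E_elec, (-138.935458 - 138.935458 / 2) / 2,
               tolerance = 1e-9)
  expect_error(binding_free_energy(
    trajectory(topo, 0, pos[1, , , drop = FALSE]),
    "receptor", "ligand", 0.5), "at least 2")
})

test_that("bootstrap SE shrinks roughly as 1/sqrt(n_frames)", {
  topo <- charge_pair(1, -1, 1)
  topo$groups <- list(receptor = 1L, ligand = 2L)
  se_at <- function(nf) {
    set.seed(99)
    pos <- array(0, c(nf, 2, 3))
    for (f in seq_len(nf)) {
      pos[f, , ] <- topo$positions
      pos[f, 2, 3] <- pos[f, 2, 3] + rnorm(1, 0, 0.05)
    }
    tr <- trajectory(topo, seq_len(nf) * 0.5, pos, array(0, c(nf, 2, 3)))
    bb <- binding_free_energy(tr, "receptor", "ligand", 0.5, n_boot = 800,
                              seed = 5, solvation = FALSE)
    unname(bb$se_bootstrap["G_binding"])
  }
  s10 <- se_at(10); s40 <- se_at(40); s160 <- se_at(160)
  expect_equal(s10 / s40, 2, tolerance = 0.5)
  expect_equal(s40 / s160, 2, tolerance = 0.5)
})

test_that("residue decomposition is an exact partition of the total", {
  set.seed(31)
  n <- 9
  topo <- particle_system(matrix(runif(3 * n, 4, 5.5), ncol = 3),
                          masses = rep(1, n), box_edge = 100,
                          charges = round(runif(n, -0.4, 0.4), 2),
                          lj_sigma = rep(0.2, n), lj_eps = runif(n, 0.1, 0.3),
                          radii = rep(0.18, n),
                          residue_ids = c(1L, 1L, 2L, 2L, 3L, 3L, 9L, 9L, 9L),
                          residue_names = c(rep("ALA", 2), rep("GLY", 2),
                                            rep("SER", 2), rep("LIG", 3)),
                          groups = list(receptor = 1:6, ligand = 7:9))
  nf <- 3
  pos <- array(runif(nf * n * 3, 4, 5.5), c(nf, n, 3))
  tr <- trajectory(topo, seq_len(nf) * 0.5, pos, array(0, c(nf, n, 3)))
  # MM-only closure is exact
  dec <- residue_decomposition(tr, "receptor", "ligand", 0.5,
                               solvation = FALSE)
  expect_lt(abs(attr(dec, "closure_residual")), 1e-6)
  expect_equal(sum(dec$contribution) + attr(dec, "closure_residual"),
               attr(dec, "G_binding"), tolerance = 1e-9)
  # with solvation (coarse grid), the per-atom partition still closes
  dec2 <- residue_decomposition(tr, "receptor", "ligand", 0.5,
                                solvation = TRUE,
                                pb_args = list(grid_spacing = 0.09))
  expect_lt(abs(attr(dec2, "closure_residual")), 1e-6)
  expect_error(residue_decomposition(tr, "receptor", "ligand", 0.5,
                                     scheme = "magic"), "unknown")
})

test_that("an uncharged LJ-free residue contributes nothing", {
  topo <- particle_system(rbind(c(5, 5, 5), c(5, 5, 5.5), c(5, 5, 6)),
                          masses = rep(1, 3), box_edge = 100,
                          charges = c(0.5, 0, -0.5),
                          residue_ids = c(1L, 2L, 9L),
                          residue_names = c("ALA", "GLY", "LIG"),
                          groups = list(receptor = 1:2, ligand = 3L))
  pos <- array(0, c(2, 3, 3))
  pos[1, , ] <- topo$positions; pos[2, , ] <- topo$positions
  tr <- trajectory(topo, c(0, 0.5), pos, array(0, c(2, 3, 3)))
  dec <- residue_decomposition(tr, "receptor", "ligand", 0.5,
                               solvation = FALSE)
  expect_equal(dec$contribution[dec$residue == "GLY2"], 0)
})

test_that("delta_g subtracts component-wise with quadrature SEs", {
  mk <- function(vals, se) {
    structure(list(G_binding = sum(vals), E_vdw = vals[1], E_elec = vals[2],
                   G_polar = vals[3], G_nonpolar = vals[4], n_frames = 5,
                   se_bootstrap = c(E_vdw = se, E_elec = se, G_polar = se,
                                    G_nonpolar = se, G_binding = se),
                   sampling_interval = 0.5,
                   settings = list(sampling_interval = 0.5, n_frames = 5,
                                   solvation = FALSE, pb_args = list(),
                                   np_args = list())),
              class = "binding_breakdown")
  }
  on <- mk(c(-10, -5, 3, -1), 0.3)
  off <- mk(c(-5, -5, 3, -1), 0.4)
  d <- delta_g(on, off)
  expect_equal(unname(d$delta["G_binding"]), -5)
  expect_equal(unname(d$delta["E_vdw"]), -5)
  expect_equal(unname(d$delta["E_elec"]), 0)
  expect_equal(unname(d$se["G_binding"]), sqrt(0.09 + 0.16))
  # identical inputs -> zeros
  expect_equal(max(abs(delta_g(on, on)$delta)), 0)
  # settings mismatch
  off$settings$sampling_interval <- 1
  expect_error(delta_g(on, off), "different settings")
})
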