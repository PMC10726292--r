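test_that("harmonic probe spring constant follows k = mu (2 pi f0)^2", {
  sys <- make_harmonic_probe(f0 = 34.5, mass = 10)
  man <- attr(sys, "manifest")
  expect_equal(man$k, 5 * (2 * pi * 34.5)^2, tolerance = 1e-12)
  expect_equal(man$k, 2.349e5, tolerance = 1e-3)
  expect_error(make_harmonic_probe(-1), "f0")
})

test_that("a neutral probe has an identically zero spectrum", {
  sys <- make_harmonic_probe(20, charge = 0)
  tr <- integrate_md(sys, sim_config(timestep = 5e-4, n_steps = 4000,
                                     sample_every = 2))
  sp <- absorption_spectrum(tr, "probe", normalization = "none")
  expect_equal(max(sp$absorption), 0)
})

test_that("probe eigenfrequency is recovered from an NVE run", {
  sys <- make_harmonic_probe(34.5)
  tr <- integrate_md(sys, sim_config(timestep = 2e-4, n_steps = 100000,
                                     sample_every = 5))
  pk <- find_peak(absorption_spectrum(tr, "probe"))
  expect_equal(unname(pk["frequency"]), 34.5, tolerance = 0.1)
})

test_that("analytic trajectories honor the seed contract", {
  comp <- data.frame(frequency = 10, amplitude = 1, axis = "z")
  t1 <- make_analytic_trajectory(comp, noise_sd = 0.5, duration = 1, seed = 1)
  t2 <- make_analytic_trajectory(comp, noise_sd = 0.5, duration = 1, seed = 1)
  t3 <- make_analytic_trajectory(comp, noise_sd = 0.5, duration = 1, seed = 2)
  expect_identical(t1$velocities, t2$velocities)
  expect_false(identical(t1$velocities, t3$velocities))
})

test_that("host-guest pre-forms exactly n_donors hydrogen bonds at t0", {
  sys <- small_host_guest()
  hb <- detect_hbonds(sys, sys$groups$donors, sys$groups$acceptors)
  # the persistent contacts are formed; the switchable ones are not
  expect_equal(nrow(hb), 4L)
  expect_setequal(hb$acceptor_residue,
                  c("TYR32", "GLN78", "GLU111", "TYR186"))

  sys2 <- make_host_guest(n_donors = 2, n_hydrophobic = 3, seed = 2)
  hb2 <- detect_hbonds(sys2, sys2$groups$donors, sys2$groups$acceptors)
  expect_equal(nrow(hb2), 2L)
})

test_that("with no donors, no bonds are detected at or below the defaults", {
  sys <- make_host_guest(n_donors = 0, n_hydrophobic = 2, seed = 3)
  expect_equal(nrow(detect_hbonds(sys, sys$groups$donors,
                                  sys$groups$acceptors)), 0L)
  expect_equal(nrow(detect_hbonds(sys, sys$groups$donors,
                                  sys$groups$acceptors,
                                  hbond_criteria(0.30, 160))), 0L)
})

test_that("the t0 interaction energy matches the requested well depth", {
  for (wd in c(-50, -30)) {
    sys <- make_host_guest(well_depth = wd, seed = 1)
    e <- mm_interaction_energy(sys, "receptor", "ligand")
    expect_equal(unname(e["E_vdw"] + e["E_elec"]), wd,
                 tolerance = abs(wd) * 0.05)
  }
})

test_that("generation is bitwise reproducible for a fixed seed", {
  s1 <- make_host_guest(seed = 4)
  s2 <- make_host_guest(seed = 4)
  expect_identical(s1$positions, s2$positions)
  expect_identical(s1$charges, s2$charges)
  expect_identical(s1$pairs_dw, s2$pairs_dw)
  expect_identical(attr(s1, "manifest"), attr(s2, "manifest"))
})

test_that("infeasible geometries are rejected", {
  expect_error(make_host_guest(n_donors = 20), "infeasible")
  expect_error(make_host_guest(n_switchable = 5), "n_switchable")
})

test_that("the manifest records the designated switchable contacts", {
  sys <- small_host_guest()
  man <- attr(sys, "manifest")
  expect_length(man$switchable_pair_ids, 2L)
  expect_true(any(grepl("GLN78", man$switchable_pair_ids)))
  expect_true(any(grepl("THR187", man$switchable_pair_ids)))
  expect_gt(man$switchable[[1]]$barrier_kJmol, 20)
  # the resting acceptor is outside criteria; the locked state inside
  for (m in man$switchable) {
    expect_gt(m$x_donor_distance_off, 0.36)
    expect_lt(m$x_donor_distance_on, 0.35)
  }
  f <- tempfile(fileext = ".json")
  write_manifest(sys, f)
  expect_true(jsonlite::validate(paste(readLines(f), collapse = "")))
})

test_that("ion counts follow the pair-count convention and neutrality", {
  solute <- particle_system(matrix(c(4, 4, 4), 1), masses = 12, box_edge = 8,
                            charges = 0, radii = 0.2)
  box <- make_toy_box(solute, 8.0, 0.15, seed = 1)
  man <- attr(box, "manifest")
  expect_equal(man$n_cations, 46L)   # round(0.15 * N_A * (8 nm)^3)
  expect_equal(man$n_anions, 46L)
  expect_equal(sum(box$charges), 0)

  solute4 <- solute; solute4$charges <- 4
  box4 <- make_toy_box(solute4, 8.0, 0.15, seed = 1)
  man4 <- attr(box4, "manifest")
  expect_equal(man4$n_anions - man4$n_cations, 4L)
  expect_equal(sum(box4$charges), 0)

  box0 <- make_toy_box(solute, 8.0, 0, seed = 1)
  expect_equal(attr(box0, "manifest")$n_cations +
                 attr(box0, "manifest")$n_anions, 0L)
})

test_that("ions respect the minimum placement distance", {
  solute <- particle_system(matrix(c(4, 4, 4), 1), masses = 12, box_edge = 8,
                            charges = 0, radii = 0.2)
  box <- make_toy_box(solute, 8.0, 0.15, seed = 2)
  d <- as.matrix(dist(box$positions))
  diag(d) <- Inf
  # minimum-image check unnecessary at these densities; direct distances
  expect_gt(min(d), 0.2)
  wide <- particle_system(rbind(c(0, 0, 0), c(0, 0, 1)), masses = c(1, 1),
                          box_edge = 8, charges = c(0, 0))
  expect_error(make_toy_box(wide, 0.5, 0.15), "exceed")
})
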