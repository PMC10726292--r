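#' Charged harmonic probe with a prescribed eigenfrequency
#'
#' A two-atom harmonic dimer oriented along z whose bond-stretch
#' eigenfrequency is exactly \code{f0}: the spring constant is
#' \eqn{k = \mu (2\pi f_0)^2} with reduced mass \eqn{\mu} (f0 in THz = 1/ps
#' gives k in kJ/mol/nm^2). Opposite partial charges make the mode
#' infrared-active, so its charge-current spectrum shows a single peak at
#' \code{f0}. The bond starts stretched by \code{excite} nm so a plain NVE
#' run oscillates deterministically.
#'
#' @param f0 eigenfrequency, THz; > 0.
#' @param mass per-atom mass, u (equal masses; reduced mass = mass/2).
#' @param charge magnitude of the opposite partial charges, e.
#' @param r0 equilibrium bond length, nm.
#' @param excite initial bond stretch, nm.
#' @param box_edge box, nm.
#' @return A \code{particle_system} with group \code{probe} and a ground-truth
#'   manifest in attribute \code{"manifest"}.
#' @export
make_harmonic_probe <- function(f0, mass = 10, charge = 0.5, r0 = 0.2,
                                excite = 0.02, box_edge = 8.0) {
  if (f0 <= 0 || mass <= 0) stop("f0 and mass must be > 0")
  mu <- mass / 2
  k <- mu * (2 * pi * f0)^2
  c0 <- box_edge / 2
  z <- (r0 + excite) / 2
  sys <- particle_system(
    positions = rbind(c(c0, c0, c0 - z), c(c0, c0, c0 + z)),
    masses = c(mass, mass), box_edge = box_edge,
    charges = c(charge, -charge),
    atom_names = c("P1", "P2"), residue_ids = c(1L, 1L),
    residue_names = c("PRB", "PRB"),
    groups = list(probe = 1:2),
    bonds = data.frame(i = 1L, j = 2L, kb = k, r0 = r0))
  attr(sys, "manifest") <- list(kind = "harmonic_probe", f0 = f0, k = k,
                                mu = mu, charge = charge, r0 = r0,
                                excite = excite)
  sys
}

#' Charged isotropic harmonic well
#'
#' A charged particle in an isotropic harmonic well (a zero-rest-length bond
#' of stiffness \eqn{k = m (2\pi f_0)^2} to a quasi-immobile heavy anchor
#' carrying the opposite charge). Every direction resonates at \code{f0}, so
#' thermal reorientation cannot detune a polarized drive: this is the
#' reference system for driven (resonant-absorption) experiments at finite
#' temperature, where a free dimer would tumble and decohere.
#'
#' @param f0 eigenfrequency, THz.
#' @param mass particle mass, u.
#' @param charge particle charge, e (anchor carries \code{-charge}).
#' @param box_edge box, nm.
#' @return A \code{particle_system} with group \code{oscillator} (the mobile
#'   particle) and a manifest.
#' @export
make_charged_well <- function(f0, mass = 10, charge = 0.5, box_edge = 8.0) {
  if (f0 <= 0 || mass <= 0) stop("f0 and mass must be > 0")
  k <- mass * (2 * pi * f0)^2
  c0 <- box_edge / 2
  sys <- particle_system(
    positions = rbind(c(c0, c0, c0), c(c0, c0, c0)),
    masses = c(1e6, mass), box_edge = box_edge,
    charges = c(-charge, charge),
    atom_names = c("AN", "P1"), residue_ids = c(1L, 1L),
    residue_names = c("WEL", "WEL"),
    groups = list(oscillator = 2L),
    bonds = data.frame(i = 1L, j = 2L, kb = k, r0 = 0))
  attr(sys, "manifest") <- list(kind = "charged_well", f0 = f0, k = k,
                                mass = mass, charge = charge)
  sys
}

#' Analytic single-particle trajectory for spectrum validation
#'
#' One charged particle whose velocity is a stated sum of cosines plus
#' optional Gaussian white noise; positions follow by exact integration of
#' the cosine terms plus a cumulative sum of the noise. Pure plumbing for
#' validating the spectra stack against closed forms.
#'
#' @param components data.frame with columns \code{frequency} (THz),
#'   \code{amplitude} (nm/ps) and \code{axis} (1, 2 or 3, or "x"/"y"/"z").
#' @param noise_sd white-noise s.d. added to each velocity component, nm/ps.
#' @param dt sampling interval, ps.
#' @param duration total time, ps.
#' @param charge particle charge, e.
#' @param seed noise seed.
#' @param box_edge box, nm.
#' @return An \code{md_trajectory} of one atom with velocities.
#' @export
make_analytic_trajectory <- function(components, noise_sd = 0, dt = 0.001,
                                     duration = 10, charge = 1, seed = 1L,
                                     box_edge = 100) {
  if (dt <= 0) stop("dt must be > 0")
  components <- as.data.frame(components)
  if (nrow(components) && is.character(components$axis))
    components$axis <- match(components$axis, c("x", "y", "z"))
  times <- seq(0, duration, by = dt)
  nt <- length(times)
  vel <- matrix(0, nt, 3L)
  pos <- matrix(0, nt, 3L)
  for (r in seq_len(nrow(components))) {
    f <- components$frequency[r]; a <- components$amplitude[r]
    ax <- components$axis[r]
    vel[, ax] <- vel[, ax] + a * cos(2 * pi * f * times)
    pos[, ax] <- pos[, ax] + if (f > 0) a * sin(2 * pi * f * times) / (2 * pi * f)
                             else a * times
  }
  if (noise_sd > 0) {
    old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
    set.seed(seed)
    noise <- matrix(stats::rnorm(3L * nt, sd = noise_sd), nt, 3L)
    vel <- vel + noise
    pos <- pos + apply(noise * dt, 2L, cumsum)
  }
  pos <- pos + box_edge / 2
  topo <- particle_system(positions = pos[1, , drop = FALSE], masses = 1,
                          box_edge = box_edge, charges = charge,
                          atom_names = "P1", residue_names = "SIG",
                          groups = list(signal = 1L))
  pa <- array(0, c(nt, 1L, 3L)); pa[, 1L, ] <- pos
  va <- array(0, c(nt, 1L, 3L)); va[, 1L, ] <- vel
  trajectory(topo, times, pa, va)
}

# ---------------------------------------------------------------------------
# host-guest toy pocket
# ---------------------------------------------------------------------------

#' Host-guest pocket toy with known ground truth
#'
#' Builds a rigid receptor cage (heavy atoms, stiff harmonic network)
#' enclosing a small polar ligand. Exactly \code{n_donors} donor-acceptor
#' pairs are pre-formed within default hydrogen-bond criteria (donor and
#' hydrogen on the ligand, acceptor on the receptor, held by a stiff
#' restraint at 0.29 nm), and \code{n_hydrophobic} apolar carbon pairs sit in
#' contact at 0.37 nm. Lennard-Jones well depths (and if necessary charges)
#' are scaled so the direct-space receptor-ligand interaction energy at t=0
#' equals \code{well_depth} within 5 percent.
#'
#' Additionally, \code{n_switchable} designated switchable contacts (0, 1 or
#' 2) are carried by one bistable acceptor on the +z (field) axis: a strongly
#' charged light acceptor (labelled GLN78) rides a quartic double-well bond
#' whose metastable state keeps it ~0.46 nm from the ligand donor (no
#' hydrogen bond) and whose deep state brings it to 0.30 nm. Two nested
#' numerical calibrations run on the assembled system: the well curvature is
#' bisected so the acceptor's small-oscillation frequency equals
#' \code{switch_f0}, and the barrier position is bisected to a 30 kJ/mol
#' barrier (~12 kT at 300 K: thermally stable over 60+ ps, verified across
#' seeds). A resonant z-polarized field boosts the thermally assisted
#' crossing enough to lock the contact within a ~40 ps arm; in the locked
#' state the acceptor simultaneously satisfies the criteria of the ligand
#' donor and of a rigid receptor donor (THR187) aimed at the calibrated deep
#' position — so the two designated "added" interactions of field-on versus
#' field-off network differencing appear as one cooperative event. Residue
#' labels mirror a glutamate-receptor pocket: acceptors TYR32, GLN78,
#' GLU111, TYR186; ligand LIG.
#'
#' @param n_donors number of persistent donor-acceptor pairs (0..8).
#' @param n_hydrophobic number of apolar contact pairs (0..8).
#' @param well_depth target direct-space binding energy at t=0, kJ/mol
#'   (negative).
#' @param seed placement jitter seed.
#' @param n_switchable number of designated switchable contacts (0, 1 or 2).
#' @param switch_f0 eigenfrequency of the switchable mode, THz.
#' @param box_edge box, nm.
#' @param switch_tuning named list overriding the switchable-contact design
#'   constants (acceptor mass/charge, well geometry, barrier target,
#'   calibration offset, recommended friction, donor-arm stiffnesses); see
#'   the methods vignette. Intended for experimentation, not routine use.
#' @return A \code{particle_system} with groups \code{ligand},
#'   \code{receptor}, \code{pocket}, \code{donors}, \code{acceptors} and a
#'   ground-truth manifest in attribute \code{"manifest"} (persistent and
#'   switchable contact ids, calibrated frequency and barrier, achieved well
#'   depth, recommended friction and cutoff).
#' @export
make_host_guest <- function(n_donors = 4, n_hydrophobic = 6,
                            well_depth = -50, seed = 1L, n_switchable = 2,
                            switch_f0 = 34.5, box_edge = 8.0,
                            switch_tuning = list()) {
  if (n_donors < 0 || n_donors > 8)
    stop("infeasible geometry: n_donors must be 0..8 for this cage size")
  if (n_hydrophobic < 0 || n_hydrophobic > 8)
    stop("infeasible geometry: n_hydrophobic must be 0..8")
  if (!n_switchable %in% 0:2) stop("n_switchable must be 0, 1 or 2")
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)

  ctr <- rep(box_edge / 2, 3)
  scaffold_mass <- 1e12  # immobile receptor scaffold (position restraint)
  tun <- utils::modifyList(
    list(m_x = 2, q_x = -4.0, q_dh = 0.2, b = 0.032, d = 0.16,
         barrier_kJmol = 30, static_f0_scale = 1.01, friction = 0.5,
         arm_k1 = 30000, arm_k2 = 30000), switch_tuning)
  pocket_res <- data.frame(name = c("TYR", "GLN", "GLU", "TYR"),
                           id = c(32L, 78L, 111L, 186L))
  atoms <- list()
  add_atom <- function(name, res_name, res_id, pos, mass, charge,
                       sigma = 0.30, eps = 0.40) {
    atoms[[length(atoms) + 1L]] <<- list(
      name = name, res_name = res_name, res_id = res_id, pos = pos,
      mass = mass, charge = charge, sigma = sigma, eps = eps)
    length(atoms)
  }
  bonds <- list(); angles <- list(); dws <- list()
  add_bond <- function(i, j, kb, r0) bonds[[length(bonds) + 1L]] <<-
    data.frame(i = i, j = j, kb = kb, r0 = r0)
  add_angle <- function(i, j, k, ka, th0) angles[[length(angles) + 1L]] <<-
    data.frame(i = i, j = j, k = k, ka = ka, theta0 = th0)

  # --- ligand core ---------------------------------------------------------
  iL0 <- add_atom("NL0", "LIG", 1L, ctr, 12, 0, eps = 0)

  # persistent donors in the xy-plane; acceptors + supports radially beyond
  donor_dirs <- if (n_donors > 0) {
    az <- 2 * pi * (seq_len(n_donors) - 1) / max(n_donors, 1) + pi / 4
    cbind(cos(az), sin(az), 0)
  } else matrix(0, 0, 3)
  iD <- iH <- iA <- integer(n_donors)
  for (kk in seq_len(n_donors)) {
    u <- donor_dirs[kk, ]
    res <- if (kk <= 4) pocket_res[kk, ] else
      data.frame(name = "ASN", id = 120L + kk)
    iD[kk] <- add_atom(paste0("ND", kk), "LIG", 1L, ctr + 0.35 * u, 14, -0.35)
    iH[kk] <- add_atom(paste0("HD", kk), "LIG", 1L, ctr + 0.45 * u, 1, 0.35,
                       sigma = 0, eps = 0)
    iA[kk] <- add_atom(paste0("OA", kk), res$name, res$id, ctr + 0.64 * u,
                       scaffold_mass, -0.45)
    add_bond(iL0, iD[kk], 20000, 0.35)
    add_bond(iD[kk], iH[kk], 25000, 0.10)
    add_angle(iL0, iD[kk], iH[kk], 1500, pi)
    add_bond(iD[kk], iA[kk], 8000, 0.29)   # engineered persistent contact
  }

  # hydrophobic pairs on tilted rings
  iCL <- iCB <- integer(n_hydrophobic)
  # apolar contacts in an equatorial band, clear of the polar switch arms
  for (m in seq_len(n_hydrophobic)) {
    elev <- if (m %% 2 == 0) 0.55 else -0.55
    az <- 2 * pi * (m - 1) / max(n_hydrophobic, 1) + pi / 6
    u <- c(cos(az) * cos(elev), sin(az) * cos(elev), sin(elev))
    iCL[m] <- add_atom(paste0("CA", m), "LIG", 1L, ctr + 0.35 * u, 12, 0)
    iCB[m] <- add_atom(paste0("CB", m), "CAG", 200L + m, ctr + 0.72 * u,
                       scaffold_mass, 0)
    add_bond(iL0, iCL[m], 20000, 0.35)
    add_bond(iCL[m], iCB[m], 30000, 0.37)  # engineered apolar contact
  }

  # structural cage ring (apolar-invisible names, heavy)
  iSR <- integer(0)
  for (m in 1:6) {
    az <- 2 * pi * (m - 1) / 6 + 0.26
    elev <- if (m %% 2 == 0) 0.45 else -0.45
    u <- c(cos(az) * cos(elev), sin(az) * cos(elev), sin(elev))
    iSR <- c(iSR, add_atom(paste0("SR", m), "CAG", 250L, ctr + 0.85 * u,
                           scaffold_mass, 0))
  }
  # supports behind each persistent acceptor tie it into the cage
  iSA <- integer(n_donors)
  for (kk in seq_len(n_donors)) {
    u <- donor_dirs[kk, ]
    res <- if (kk <= 4) pocket_res[kk, ] else
      data.frame(name = "ASN", id = 120L + kk)
    iSA[kk] <- add_atom(paste0("SA", kk), res$name, res$id, ctr + 0.85 * u,
                        scaffold_mass, 0)
    add_bond(iA[kk], iSA[kk], 30000, 0.21)
    # first-order orientational anchor: fixes the donor direction relative
    # to the rigid support, suppressing free rigid-body rotation of the
    # ligand (all plain distance restraints are only second-order in it)
    add_angle(iSA[kk], iA[kk], iD[kk], 1000, pi)
  }

  # --- switchable contact: one driven acceptor, n_switchable donors --------
  # A single bistable acceptor rides a quartic double-well arm on the +z
  # (field) axis. The designated ligand donors are tilted a few degrees off
  # the axis so that when the acceptor drops into its deep state it
  # simultaneously satisfies the hydrogen-bond criteria of every designated
  # donor: the "added" contacts appear together, as one resonance-driven
  # event.
  sw_b <- tun$b; sw_d <- tun$d
  q_x <- tun$q_x; m_x <- tun$m_x
  r_dw0 <- 0.40                      # nominal metastable X-anchor distance
  iDs <- iHs <- integer(n_switchable)
  iX <- iC1 <- iC2 <- 0L
  sw_manifest <- list()
  if (n_switchable > 0) {
    # one collinear ligand donor arm on the field axis (no azimuthal cone
    # degeneracy: core-donor-hydrogen held at 180 degrees), and, for the
    # second designated contact, a rigid receptor donor aimed at the lock
    # site: when the acceptor drops in, it accepts from the ligand donor
    # and from the receptor donor in the same event
    z_don <- 0.35
    z_lock <- z_don + 0.30            # locked X is 0.30 nm from the donor
    z_free <- z_lock + sw_d
    z_anchor <- z_free + r_dw0
    iDs[1] <- add_atom("NDS1", "LIG", 1L, ctr + c(0, 0, z_don), 14, 0,
                       sigma = 0.24)
    iHs[1] <- add_atom("HDS1", "LIG", 1L, ctr + c(0, 0, 0.45), 1,
                       tun$q_dh, sigma = 0.06, eps = 0.1)
    add_bond(iL0, iDs[1], tun$arm_k1, 0.35)
    add_bond(iDs[1], iHs[1], tun$arm_k2, 0.10)
    add_angle(iL0, iDs[1], iHs[1], 1500, pi)
    if (n_switchable >= 2) {
      # fixed receptor donor: 0.30 nm from the lock site, > 0.36 nm (and at
      # a sub-threshold approach angle) from the resting acceptor; soft LJ
      # so it never deflects the acceptor off its path; re-aimed at the
      # calibrated deep minimum after the well calibration
      p_lock <- ctr + c(0, 0, z_lock)
      p_dr <- p_lock + c(0.296, 0, -0.05)
      p_hr <- p_dr + 0.10 * (p_lock - p_dr) / 0.30
      iDs[2] <- add_atom("NDR1", "THR", 187L, p_dr, scaffold_mass, 0,
                         sigma = 0.15, eps = 0.05)
      iHs[2] <- add_atom("HDR1", "THR", 187L, p_hr, scaffold_mass, 0,
                         sigma = 0, eps = 0)
      add_bond(iDs[2], iHs[2], 30000, 0.10)
    }
    k_target <- m_x * (2 * pi * switch_f0 * tun$static_f0_scale)^2
    a4 <- k_target / (4 * sw_b * sw_d)
    iX <- add_atom("OX1", "GLN", 78L, ctr + c(0, 0, z_free), m_x, q_x,
                   eps = 0.40)
    iC1 <- add_atom("SC1", "CAG", 261L, ctr + c(0, 0, z_anchor),
                    scaffold_mass, 0)
    iC2 <- add_atom("SD1", "CAG", 261L, ctr + c(0, 0, z_anchor + 0.35),
                    scaffold_mass, 0)
    dws[[length(dws) + 1L]] <- data.frame(i = iC1, j = iX, a4 = a4,
                                          r0 = r_dw0, b = sw_b, d = sw_d)
    add_bond(iC1, iC2, 30000, 0.35)
    add_angle(iC2, iC1, iX, 15000, pi)
  }
  # fixed central compensator charges: cancel the persistent-acceptor ring's
  # electrostatic gradient along the switch paths so the barrier is set by
  # the double-well alone (no LJ, so they never clash with the ligand core)
  if (n_switchable > 0) {
    add_atom("SP1", "CAG", 259L, ctr + c(0.12, 0, 0), scaffold_mass, 0.225,
             sigma = 0, eps = 0)
    add_atom("SP2", "CAG", 259L, ctr - c(0.12, 0, 0), scaffold_mass, 0.225,
             sigma = 0, eps = 0)
  }

  # --- assemble ------------------------------------------------------------
  n <- length(atoms)
  pos <- do.call(rbind, lapply(atoms, `[[`, "pos"))
  # small seeded jitter on structural atoms (never on engineered contacts)
  jit <- which(vapply(atoms, function(a) startsWith(a$name, "SR"), TRUE))
  pos[jit, ] <- pos[jit, ] + matrix(stats::runif(3 * length(jit), -0.02, 0.02),
                                    ncol = 3)
  sysdat <- list(
    names = vapply(atoms, `[[`, "", "name"),
    res_names = vapply(atoms, `[[`, "", "res_name"),
    res_ids = vapply(atoms, function(a) as.integer(a$res_id), 1L),
    masses = vapply(atoms, `[[`, 1, "mass"),
    charges = vapply(atoms, `[[`, 1, "charge"),
    sigma = vapply(atoms, `[[`, 1, "sigma"),
    eps = vapply(atoms, `[[`, 1, "eps"))

  # semi-rigid ligand: angles between every pair of arms rooted at the core
  # (theta0 = as-constructed angle, so t = 0 is strain-free)
  arm_roots <- c(iD, iCL, if (n_switchable > 0) iDs[1])
  arm_roots <- arm_roots[!is.na(arm_roots) & arm_roots > 0]
  if (length(arm_roots) > 1) {
    for (a in seq_len(length(arm_roots) - 1L))
      for (b2 in (a + 1L):length(arm_roots)) {
        va <- pos[arm_roots[a], ] - pos[iL0, ]
        vb <- pos[arm_roots[b2], ] - pos[iL0, ]
        th0 <- acos(max(-1, min(1, sum(va * vb) /
                                  sqrt(sum(va^2) * sum(vb^2)))))
        add_angle(arm_roots[a], iL0, arm_roots[b2], 1000, th0)
      }
  }

  ligand <- which(sysdat$res_names == "LIG")
  receptor <- setdiff(seq_len(n), ligand)
  pocket <- which(paste0(sysdat$res_names, sysdat$res_ids) %in%
                    paste0(pocket_res$name, pocket_res$id))
  donors_all <- c(iD, iDs)
  acceptors_all <- c(iA, if (iX > 0) iX)

  sys <- particle_system(
    positions = pos, masses = sysdat$masses, box_edge = box_edge,
    charges = sysdat$charges, atom_names = sysdat$names,
    residue_ids = sysdat$res_ids, residue_names = sysdat$res_names,
    groups = list(ligand = ligand, receptor = receptor, pocket = pocket,
                  donors = donors_all, acceptors = acceptors_all),
    bonds = do.call(rbind, bonds), angles = do.call(rbind, angles),
    pairs_dw = if (length(dws)) do.call(rbind, dws) else NULL,
    lj_sigma = sysdat$sigma, lj_eps = sysdat$eps,
    radii = ifelse(startsWith(sysdat$names, "H"), 0.11,
                   ifelse(startsWith(sysdat$names, "OX"), 0.45, 0.17)))

  # --- calibrate the direct-space well depth at t = 0 ----------------------
  # Electrostatics first: if the engineered charges overshoot the target,
  # rescale them -- but never the switchable units (acceptor X and its donor
  # unit), whose charges set the resonant drive coupling and the bistable
  # tilt. With exempt charges q_e and scalable charges s*q_n the cross-group
  # electrostatic energy is E(s) = E_ee + s E_en + s^2 E_nn.
  e0 <- mm_interaction_energy(sys, receptor, ligand)
  charge_scale <- 1
  if (e0[["E_elec"]] < 0.8 * well_depth) {
    # only the driven acceptor's charge is load-bearing for the resonant
    # coupling; everything else may be rescaled (the switch-well calibration
    # runs afterwards and absorbs the change)
    exempt <- iX[iX > 0]
    elec_with <- function(q) {
      s2 <- sys; s2$charges <- q
      mm_interaction_energy(s2, receptor, ligand)[["E_elec"]]
    }
    qe <- sys$charges; qe[setdiff(seq_along(qe), exempt)] <- 0
    qn <- sys$charges; qn[exempt] <- 0
    e_ee <- elec_with(qe)
    e_nn <- elec_with(qn)
    e_en <- e0[["E_elec"]] - e_ee - e_nn
    fshort <- function(s) e_ee + s * e_en + s^2 * e_nn - 0.8 * well_depth
    if (fshort(0) < 0) {
      warning("switch-unit electrostatics alone exceed the well-depth ",
              "target; charges left unscaled")
    } else if (fshort(1) < 0) {
      charge_scale <- stats::uniroot(fshort, c(0, 1), tol = 1e-10)$root
      keep <- setdiff(seq_len(n), exempt)
      sys$charges[keep] <- sys$charges[keep] * charge_scale
      e0 <- mm_interaction_energy(sys, receptor, ligand)
    }
  }
  target_vdw <- well_depth - e0[["E_elec"]]
  if (e0[["E_vdw"]] != 0 && target_vdw / e0[["E_vdw"]] > 0)
    sys$lj_eps <- sys$lj_eps * (target_vdw / e0[["E_vdw"]])

  # --- numeric calibration of the switchable wells -------------------------
  # Move each switchable acceptor along its arm axis through the fully
  # assembled system (production cutoff), find the metastable minimum, and
  # iterate the double-well stiffness until the total curvature matches
  # m_x (2 pi f0)^2. Then reseat the acceptor at the calibrated minimum.
  if (n_switchable > 0) {
    cal_cfg <- sim_config(cutoff = min(2.0, box_edge / 2))
    k_target <- m_x * (2 * pi * switch_f0 * tun$static_f0_scale)^2
    {
      # outer bisection on the barrier position b: the frequency calibration
      # (inner bisection on a4) runs at each candidate so the reported
      # barrier always refers to a correctly tuned metastable well
      blo <- 0.008; bhi <- 0.08
      row <- which(sys$pairs_dw$j == iX)
      p_anchor <- sys$positions[iC1, ]
      u_arm <- c(0, 0, -1)           # the arm axis, anchor towards the core
      vat2 <- function(r_cx, a4v, bv) {
        s2 <- sys
        s2$pairs_dw$a4[row] <- a4v
        s2$pairs_dw$b[row] <- bv
        s2$positions[iX, ] <- p_anchor + r_cx * u_arm
        compute_forces(s2, cal_cfg)$potential_energy
      }
      # nested calibration: inner bisection on a4 tunes the metastable-well
      # curvature (eigenfrequency); outer bisection on the barrier position
      # b tunes the measured barrier height to tun$barrier_kJmol
      h <- 2e-4
      calibrate_well <- function(bv) {
        a4_nom <- k_target / (4 * bv * sw_d)
        kcurv <- function(a4v) {
          opt <- stats::optimize(vat2, c(r_dw0 - 0.08, r_dw0 + bv - 0.004),
                                 a4v = a4v, bv = bv, tol = 1e-9)
          rm <- opt$minimum
          if (rm < r_dw0 - 0.078 || rm > r_dw0 + bv - 0.006) return(NA_real_)
          list(k = (vat2(rm + h, a4v, bv) - 2 * vat2(rm, a4v, bv) +
                      vat2(rm - h, a4v, bv)) / h^2, r = rm)
        }
        lo <- 0.3 * a4_nom; hi <- 6 * a4_nom
        kc_ok <- NULL
        for (it in 1:40) {
          mid <- 0.5 * (lo + hi)
          kc <- kcurv(mid)
          if (is.list(kc)) kc_ok <- kc
          if (!is.list(kc) || kc$k < k_target) lo <- mid else hi <- mid
          if ((hi - lo) < 1e-5 * a4_nom) break
        }
        a4v <- 0.5 * (lo + hi)
        kc <- kcurv(a4v)
        if (!is.list(kc)) return(NULL)
        r_min <- kc$r
        vt <- function(r_cx) vat2(r_cx, a4v, bv)
        bar <- stats::optimize(vt, c(r_min, r_dw0 + sw_d), maximum = TRUE,
                               tol = 1e-8)
        deep <- stats::optimize(vt, c(bar$maximum, r_dw0 + sw_d + 0.06),
                                tol = 1e-8)
        list(a4 = a4v, r_min = r_min, bar = bar, deep = deep,
             barrier = bar$objective - vt(r_min))
      }
      cal <- NULL
      for (it in 1:25) {
        bm <- 0.5 * (blo + bhi)
        cc <- calibrate_well(bm)
        if (is.null(cc) || cc$barrier > tun$barrier_kJmol) bhi <- bm
        else { blo <- bm; cal <- cc }
        if (!is.null(cc)) cal <- cc
        if ((bhi - blo) < 1e-4) break
      }
      if (is.null(cal))
        stop("switch calibration: metastable well lost")
      sw_b_used <- 0.5 * (blo + bhi)
      cal <- calibrate_well(sw_b_used)
      sys$pairs_dw$a4[row] <- cal$a4
      sys$pairs_dw$b[row] <- sw_b_used
      r_min <- cal$r_min
      bar <- cal$bar; deep <- cal$deep
      vtot <- function(r_cx) vat2(r_cx, cal$a4, sw_b_used)
      sys$positions[iX, ] <- p_anchor + r_min * u_arm
      if (n_switchable >= 2) {
        # re-aim the fixed receptor donor at the calibrated deep minimum
        p_lock_cal <- p_anchor + deep$minimum * u_arm
        p_dr <- p_lock_cal + c(0.296, 0, -0.05)
        sys$positions[iDs[2], ] <- p_dr
        sys$positions[iHs[2], ] <- p_dr + 0.10 * (p_lock_cal - p_dr) / 0.30
      }
      for (s in seq_len(n_switchable)) {
        p_don <- sys$positions[iDs[s], ]
        dist_to_don <- function(r_cx)
          sqrt(sum((p_anchor + r_cx * u_arm - p_don)^2))
        sw_manifest[[s]] <- list(
          donor_atom = iDs[s], acceptor_atom = iX,
          acceptor_residue = "GLN78",
          f0_THz = switch_f0,
          a4 = sys$pairs_dw$a4[row],
          b = sw_b_used,
          r_metastable = r_min,
          x_donor_distance_off = dist_to_don(r_min),
          x_donor_distance_on = dist_to_don(deep$minimum),
          barrier_kJmol = bar$objective - vtot(r_min),
          deep_depth_kJmol = deep$objective - vtot(r_min))
      }
    }
  }
  e_final <- mm_interaction_energy(sys, receptor, ligand)

  hb_ids <- if (n_donors > 0)
    sprintf("hbond:LIG1.%d>%s%d.%d", iD,
            sysdat$res_names[iA], sysdat$res_ids[iA], iA) else character(0)
  sw_ids <- if (n_switchable > 0)
    sprintf("hbond:%s%d.%d>%s%d.%d", sysdat$res_names[iDs],
            sysdat$res_ids[iDs], iDs,
            sysdat$res_names[iX], sysdat$res_ids[iX], iX) else character(0)
  hy_ids <- if (n_hydrophobic > 0)
    vapply(seq_len(n_hydrophobic), function(m)
      paste0("hydro:", paste(sort(c("LIG1", paste0("CAG", 200L + m))),
                             collapse = "~")), "") else character(0)

  attr(sys, "manifest") <- list(
    kind = "host_guest", seed = seed, n_donors = n_donors,
    n_hydrophobic = n_hydrophobic, n_switchable = n_switchable,
    switch_f0_THz = switch_f0,
    donor_pair_ids = hb_ids, switchable_pair_ids = sw_ids,
    hydrophobic_pair_ids = hy_ids,
    well_depth_target = well_depth, charge_scale = charge_scale,
    well_depth_achieved = unname(e_final[["E_vdw"]] + e_final[["E_elec"]]),
    switchable = sw_manifest,
    recommended_friction = tun$friction,
    recommended_cutoff = min(2.0, box_edge / 2))
  sys
}

#' Surround a solute with monovalent ions in a cubic box
#'
#' Point-particle K+/Cl- ions at the pair count \code{round(c N_A V)} for
#' concentration \code{salt_molar}, with the anion/cation split adjusted so
#' the total system charge is zero (no explicit water; solvation is handled
#' by the implicit-solvent binding terms).
#'
#' @param solute a \code{particle_system}.
#' @param box_edge cubic box, nm; must exceed the solute extent.
#' @param salt_molar salt concentration, mol/L.
#' @param seed placement seed.
#' @param min_dist minimum ion-atom and ion-ion distance, nm.
#' @return A \code{particle_system} with the solute centered and ions added;
#'   groups gain \code{solute} and \code{ions}; manifest records counts and
#'   the pair-count convention.
#' @export
make_toy_box <- function(solute, box_edge, salt_molar = 0.15, seed = 1L,
                         min_dist = 0.25) {
  ext <- apply(solute$positions, 2L, function(x) diff(range(x)))
  if (any(ext >= box_edge))
    stop("box_edge must exceed the solute extent (", max(ext), " nm)")
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  vol_L <- box_edge^3 * 1e-24                   # nm^3 -> L
  n_pairs <- round(salt_molar * md_constants$avogadro * vol_L)
  qnet <- round(sum(solute$charges))
  n_cat <- n_pairs + max(0L, -qnet)
  n_an <- n_pairs + max(0L, qnet)
  if (n_cat < 0 || n_an < 0)
    stop("cannot neutralize the solute with non-negative ion counts")
  ctr_shift <- box_edge / 2 - colMeans(solute$positions)
  spos <- sweep(solute$positions, 2L, ctr_shift, `+`)
  all_pos <- spos
  ion_pos <- matrix(0, 0, 3)
  placed <- 0L
  attempts <- 0L
  while (placed < n_cat + n_an) {
    if (attempts > 20000L)
      stop("could not place ions without overlap; enlarge the box")
    attempts <- attempts + 1L
    p <- stats::runif(3, 0, box_edge)
    d <- sweep(all_pos, 2L, p)
    d <- d - box_edge * round(d / box_edge)
    if (min(sqrt(rowSums(d^2))) < min_dist) next
    ion_pos <- rbind(ion_pos, p)
    all_pos <- rbind(all_pos, p)
    placed <- placed + 1L
  }
  n_sol <- solute$n_atoms
  ion_names <- c(rep("K", n_cat), rep("CL", n_an))
  sys <- particle_system(
    positions = all_pos,
    masses = c(solute$masses, rep(39.098, n_cat), rep(35.45, n_an)),
    box_edge = box_edge,
    charges = c(solute$charges, rep(1, n_cat), rep(-1, n_an)),
    velocities = rbind(solute$velocities, matrix(0, n_cat + n_an, 3)),
    atom_names = c(solute$atom_names, ion_names),
    residue_ids = c(solute$residue_ids,
                    seq_len(n_cat + n_an) + max(solute$residue_ids)),
    residue_names = c(solute$residue_names, ion_names),
    groups = c(solute$groups,
               list(solute = seq_len(n_sol),
                    ions = n_sol + seq_len(n_cat + n_an))),
    bonds = solute$bonds, angles = solute$angles, pairs_dw = solute$pairs_dw,
    lj_sigma = c(solute$lj_sigma, rep(0.3, n_cat + n_an)),
    lj_eps = c(solute$lj_eps, rep(0.4, n_cat + n_an)),
    radii = c(solute$radii, rep(0.17, n_cat + n_an)))
  attr(sys, "manifest") <- list(
    kind = "toy_box", seed = seed, salt_molar = salt_molar,
    convention = "pairs = round(c * N_A * V); anions adjusted for neutrality",
    n_cations = n_cat, n_anions = n_an, solute_net_charge = qnet)
  sys
}

#' Write a generator's ground-truth manifest as JSON
#'
#' @param system a generated \code{particle_system}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(system, path) {
  man <- attr(system, "manifest")
  if (is.null(man)) stop("system carries no manifest")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
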