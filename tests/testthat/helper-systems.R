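# small systems and independent oracles used across the suite

# two point charges, no LJ, in a large box
charge_pair <- function(q1, q2, r, box = 100) {
  particle_system(positions = rbind(c(box/2, box/2, box/2),
                                    c(box/2, box/2, box/2 + r)),
                  masses = c(1, 1), box_edge = box, charges = c(q1, q2))
}

# LJ dimer at distance r
lj_pair <- function(r, sigma = 0.3, eps = 1, box = 100) {
  particle_system(positions = rbind(c(box/2, box/2, box/2),
                                    c(box/2, box/2, box/2 + r)),
                  masses = c(1, 1), box_edge = box,
                  lj_sigma = rep(sigma, 2), lj_eps = rep(eps, 2))
}

# randomized small system with bonds, angles, LJ and charges
random_system <- function(n = 20, seed = 42, box = 4) {
  set.seed(seed)
  repeat {
    pos <- matrix(runif(3 * n, box/2 - 0.9, box/2 + 0.9), ncol = 3)
    if (min(dist(pos)) > 0.15) break
  }
  particle_system(
    positions = pos, masses = runif(n, 1, 20), box_edge = box,
    charges = round(runif(n, -0.5, 0.5), 3),
    lj_sigma = rep(0.25, n), lj_eps = runif(n, 0.05, 0.4),
    bonds = data.frame(i = 1:4, j = 5:8, kb = runif(4, 500, 2000),
                       r0 = runif(4, 0.3, 0.6)),
    angles = data.frame(i = 1:2, j = 3:4, k = 5:6,
                        ka = runif(2, 50, 200), theta0 = runif(2, 1, 2.5)))
}

# independent O(N^2) minimum-image nonbonded energy (no exclusions assumed)
brute_force_nonbonded <- function(sys, cutoff) {
  ex <- thzbind:::nonbonded_exclusions(sys)
  exs <- if (nrow(ex)) paste(ex[, 1], ex[, 2]) else character(0)
  e_lj <- 0; e_coul <- 0
  n <- sys$n_atoms
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (paste(i, j) %in% exs) next
    d <- sys$positions[i, ] - sys$positions[j, ]
    d <- d - sys$box_edge * round(d / sys$box_edge)
    r <- sqrt(sum(d^2))
    if (r > cutoff) next
    if (sys$lj_eps[i] > 0 && sys$lj_eps[j] > 0) {
      sij <- (sys$lj_sigma[i] + sys$lj_sigma[j]) / 2
      eij <- sqrt(sys$lj_eps[i] * sys$lj_eps[j])
      e_lj <- e_lj + 4 * eij * ((sij / r)^12 - (sij / r)^6)
    }
    if (sys$charges[i] != 0 && sys$charges[j] != 0)
      e_coul <- e_coul + 138.935458 * sys$charges[i] * sys$charges[j] / r
  }
  c(lj = e_lj, coulomb = e_coul)
}

# hand-built trajectory: one donor/acceptor pair whose distance follows a
# prescribed sequence (bond formed when distance small, angle 180)
crafted_hbond_traj <- function(dists, box = 10) {
  n_frames <- length(dists)
  topo <- particle_system(
    positions = rbind(c(5, 5, 5), c(5, 5, 5.1), c(5, 5, 5.3)),
    masses = c(14, 1, 16), box_edge = box,
    atom_names = c("ND", "HD", "OA"),
    residue_ids = c(1L, 1L, 2L), residue_names = c("LIG", "LIG", "REC"),
    bonds = data.frame(i = 1L, j = 2L, kb = 1000, r0 = 0.1))
  pos <- array(0, c(n_frames, 3, 3))
  for (f in seq_len(n_frames)) {
    pos[f, 1, ] <- c(5, 5, 5)
    pos[f, 2, ] <- c(5, 5, 5.1)
    pos[f, 3, ] <- c(5, 5, 5 + dists[f])
  }
  trajectory(topo, seq_len(n_frames) * 0.1, pos,
             array(0, c(n_frames, 3, 3)))
}

# tiny host-guest used where full calibration cost is unnecessary
small_host_guest <- function(seed = 1)
  make_host_guest(n_donors = 4, n_hydrophobic = 6, seed = seed)
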