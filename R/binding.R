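#' Polar (Poisson-Boltzmann) solvation free energy
#'
#' Finite-difference linearized Poisson-Boltzmann reaction-field energy of an
#' atom subset: the solute interior (union of atom spheres) gets
#' \code{eps_solute}, the exterior \code{eps_solvent}; the energy is the
#' heterogeneous-minus-homogeneous grid solution, so the discrete
#' self-energy cancels and the result converges to the continuum limit as
#' the grid is refined. Zero ionic strength by default; \code{kappa} adds
#' linear Debye-Hueckel screening.
#'
#' @param system a \code{particle_system} with charges and radii.
#' @param group atom indices or group name; default all atoms.
#' @param grid_spacing grid step, nm. Default 0.05; > 0.1 warns.
#' @param eps_solute,eps_solvent dielectric constants. Defaults 2 and 80.
#' @param margin grid margin beyond the solute, nm. Default 0.8.
#' @param kappa inverse Debye length, 1/nm. Default 0 (no screening).
#' @param maxiter,tol SOR iteration cap and relative tolerance.
#' @return List with \code{energy} (kJ/mol), \code{per_atom} energies
#'   (kJ/mol, group order) and solver \code{iterations}.
#' @export
polar_solvation <- function(system, group = NULL, grid_spacing = 0.05,
                            eps_solute = 2, eps_solvent = 80, margin = 0.8,
                            kappa = 0, maxiter = 10000L, tol = 1e-6) {
  idx <- if (is.null(group)) seq_len(system$n_atoms)
         else resolve_group(system, group)
  if (grid_spacing > 0.1)
    warning("grid_spacing ", grid_spacing,
            " nm is coarse (> 0.1 nm); expect low accuracy")
  if (any(system$radii[idx] <= 0))
    stop("all atoms in the PB solute need positive radii")
  ext <- apply(system$positions[idx, , drop = FALSE], 2L,
               function(x) diff(range(x))) + 2 * (max(system$radii[idx]) + margin)
  if (prod(ceiling(ext / grid_spacing) + 1) > 3e7)
    stop("PB grid would exceed 3e7 nodes; the solute coordinates look ",
         "divergent or the grid spacing is too fine")
  .cpp_pb_solvation(system$positions[idx, , drop = FALSE],
                    system$charges[idx], system$radii[idx],
                    grid_spacing, margin, eps_solute, eps_solvent,
                    kappa, as.integer(maxiter), tol)
}

#' Molecular-mechanics receptor-ligand interaction energy
#'
#' Sums Lennard-Jones and Coulomb terms over all receptor-ligand atom pairs
#' of one configuration, with no cutoff (minimum-image convention; the
#' single-trajectory MM-PBSA convention takes complex, receptor and ligand
#' coordinates from the same frame).
#'
#' @param system a \code{particle_system} holding the frame.
#' @param receptor,ligand disjoint atom-index vectors or group names.
#' @return Named numeric \code{c(E_vdw =, E_elec =)} in kJ/mol.
#' @export
mm_interaction_energy <- function(system, receptor, ligand) {
  pa <- mm_pair_energies(system, receptor, ligand)
  c(E_vdw = sum(pa$vdw), E_elec = sum(pa$elec))
}

# per-receptor-atom LJ/Coulomb sums against all ligand atoms
mm_pair_energies <- function(system, receptor, ligand) {
  rec <- resolve_group(system, receptor)
  lig <- resolve_group(system, ligand)
  if (length(intersect(rec, lig)))
    stop("receptor and ligand groups must be disjoint")
  nv <- numeric(length(rec)); ne <- numeric(length(rec))
  if (!length(rec) || !length(lig))
    return(list(vdw = nv, elec = ne, receptor = rec))
  box <- system$box_edge
  pl <- system$positions[lig, , drop = FALSE]
  ql <- system$charges[lig]
  sl <- system$lj_sigma[lig]; el <- system$lj_eps[lig]
  for (m in seq_along(rec)) {
    i <- rec[m]
    d <- sweep(pl, 2L, system$positions[i, ], `-`)
    d <- d - box * round(d / box)
    r2 <- rowSums(d^2)
    if (any(r2 < 1e-12))
      stop("singularity: receptor atom ", i, " overlaps a ligand atom")
    qq <- system$charges[i] * ql
    hasq <- qq != 0
    if (any(hasq))
      ne[m] <- md_constants$coulomb * sum(qq[hasq] / sqrt(r2[hasq]))
    eij <- sqrt(system$lj_eps[i] * el)
    hasl <- eij > 0
    if (any(hasl)) {
      sij <- 0.5 * (system$lj_sigma[i] + sl[hasl])
      sr6 <- (sij^2 / r2[hasl])^3
      nv[m] <- sum(4 * eij[hasl] * sr6 * (sr6 - 1))
    }
  }
  list(vdw = nv, elec = ne, receptor = rec)
}

frames_at_interval <- function(traj, sampling_interval, window = NULL) {
  window <- check_window(traj, window)
  t0 <- traj$times[window[1]]
  keep <- window[
    abs(((traj$times[window] - t0) / sampling_interval) -
          round((traj$times[window] - t0) / sampling_interval)) < 1e-6]
  if (!length(keep)) window[1] else keep
}

#' MM-PBSA-style binding free energy over a trajectory
#'
#' Single-trajectory end-state estimate. Per sampled frame,
#' \deqn{\Delta G = E_{vdw} + E_{elec} + [G_{polar}(C) - G_{polar}(R) -
#' G_{polar}(L)] + [G_{np}(C) - G_{np}(R) - G_{np}(L)]}
#' with receptor (R), ligand (L) and complex (C) coordinates from the same
#' frame. The report gives time averages and seeded bootstrap standard
#' errors (resampling frames with replacement). The entropy term is omitted:
#' the decomposition has exactly the four terms above.
#'
#' @param traj an \code{md_trajectory}.
#' @param receptor,ligand atom index vectors or group names.
#' @param sampling_interval frame sampling interval, ps.
#' @param window integer frame indices to sample within; default all.
#' @param n_boot bootstrap resamples. Default 1000.
#' @param seed bootstrap seed.
#' @param solvation logical: include PB + SASA terms (default TRUE). With
#'   \code{FALSE} only the molecular-mechanics terms are computed (useful
#'   against a direct pair-sum oracle).
#' @param pb_args,np_args argument lists passed on to
#'   \code{\link{polar_solvation}} / \code{\link{nonpolar_solvation}}.
#' @return A \code{binding_breakdown}: G_binding, E_vdw, E_elec, G_polar,
#'   G_nonpolar (kJ/mol), n_frames, per-component \code{se_bootstrap},
#'   \code{sampling_interval}; per-frame component matrix in attribute
#'   \code{"frames"}.
#' @export
binding_free_energy <- function(traj, receptor, ligand, sampling_interval,
                                window = NULL, n_boot = 1000L, seed = 1L,
                                solvation = TRUE, pb_args = list(),
                                np_args = list()) {
  frames <- frames_at_interval(traj, sampling_interval, window)
  if (length(frames) < 2L)
    stop("need at least 2 sampled frames (got ", length(frames), ")")
  rec <- resolve_group(traj$topology, receptor)
  lig <- resolve_group(traj$topology, ligand)
  comp <- matrix(0, length(frames), 4L,
                 dimnames = list(NULL, c("E_vdw", "E_elec", "G_polar",
                                         "G_nonpolar")))
  for (fi in seq_along(frames)) {
    sys <- system_at_frame(traj, frames[fi])
    mm <- mm_interaction_energy(sys, rec, lig)
    comp[fi, "E_vdw"] <- mm["E_vdw"]
    comp[fi, "E_elec"] <- mm["E_elec"]
    if (solvation) {
      gp <- function(g) do.call(polar_solvation,
                                c(list(sys, group = g), pb_args))$energy
      gn <- function(g) do.call(nonpolar_solvation,
                                c(list(sys, group = g), np_args))$energy
      comp[fi, "G_polar"] <- gp(c(rec, lig)) - gp(rec) - gp(lig)
      comp[fi, "G_nonpolar"] <- gn(c(rec, lig)) - gn(rec) - gn(lig)
    }
  }
  means <- colMeans(comp)
  boot <- bootstrap_se(cbind(comp, G_binding = rowSums(comp)), n_boot, seed)
  res <- structure(list(
    G_binding = sum(means),
    E_vdw = unname(means["E_vdw"]), E_elec = unname(means["E_elec"]),
    G_polar = unname(means["G_polar"]),
    G_nonpolar = unname(means["G_nonpolar"]),
    n_frames = length(frames), se_bootstrap = boot,
    sampling_interval = sampling_interval,
    settings = list(sampling_interval = sampling_interval,
                    n_frames = length(frames), solvation = solvation,
                    pb_args = pb_args, np_args = np_args)
  ), class = "binding_breakdown")
  attr(res, "frames") <- comp
  attr(res, "frame_index") <- frames
  stopifnot(abs(res$G_binding -
                  (res$E_vdw + res$E_elec + res$G_polar + res$G_nonpolar)) < 1e-6)
  res
}

bootstrap_se <- function(mat, n_boot, seed) {
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  nf <- nrow(mat)
  bm <- matrix(0, n_boot, ncol(mat), dimnames = list(NULL, colnames(mat)))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nf, nf, replace = TRUE)
    bm[b, ] <- colMeans(mat[idx, , drop = FALSE])
  }
  apply(bm, 2L, stats::sd)
}

#' @export
print.binding_breakdown <- function(x, ...) {
  cat("<binding_breakdown> over", x$n_frames, "frames (interval",
      x$sampling_interval, "ps)\n")
  comp <- c(E_vdw = x$E_vdw, E_elec = x$E_elec, G_polar = x$G_polar,
            G_nonpolar = x$G_nonpolar, G_binding = x$G_binding)
  se <- x$se_bootstrap[names(comp)]
  for (n in names(comp))
    cat(sprintf("  %-10s %10.3f +/- %.3f kJ/mol\n", n, comp[[n]], se[[n]]))
  invisible(x)
}

#' Per-residue decomposition of the binding free energy
#'
#' Each receptor residue receives the exact pairwise attribution of its
#' atoms' LJ + Coulomb interactions with the ligand, plus its atoms'
#' reaction-field difference (complex minus receptor-alone) and surface-area
#' difference; the ligand's own solvation difference is reported under the
#' ligand residue label. The contributions partition the total:
#' \code{sum(contributions) + closure_residual = G_binding} with a residual
#' at floating-point level.
#'
#' @inheritParams binding_free_energy
#' @param scheme attribution scheme; only \code{"per-atom"} (exact
#'   partition) is defined.
#' @return A \code{residue_decomposition}: data.frame of per-residue
#'   contributions (kJ/mol), plus \code{G_binding} and \code{closure_residual}
#'   attributes.
#' @export
residue_decomposition <- function(traj, receptor, ligand, sampling_interval,
                                  window = NULL, scheme = "per-atom",
                                  solvation = TRUE, pb_args = list(),
                                  np_args = list()) {
  if (!identical(scheme, "per-atom"))
    stop("unknown decomposition scheme: ", scheme)
  frames <- frames_at_interval(traj, sampling_interval, window)
  rec <- resolve_group(traj$topology, receptor)
  lig <- resolve_group(traj$topology, ligand)
  sys0 <- traj$topology
  labels <- c(res_label(sys0, rec), res_label(sys0, lig))
  atom_idx <- c(rec, lig)
  contrib <- matrix(0, length(frames), length(atom_idx))
  total <- numeric(length(frames))
  gamma <- if (!is.null(np_args$gamma)) np_args$gamma else 2.27
  for (fi in seq_along(frames)) {
    sys <- system_at_frame(traj, frames[fi])
    pa <- mm_pair_energies(sys, rec, lig)
    per_atom <- c(pa$vdw + pa$elec, numeric(length(lig)))
    if (solvation) {
      gp <- function(g) do.call(polar_solvation,
                                c(list(sys, group = g), pb_args))$per_atom
      np_args_local <- np_args; np_args_local$gamma <- NULL
      gs <- function(g) do.call(nonpolar_solvation,
                                c(list(sys, group = g), np_args_local))$per_atom
      pol_c <- gp(c(rec, lig)); pol_r <- gp(rec); pol_l <- gp(lig)
      sas_c <- gs(c(rec, lig)); sas_r <- gs(rec); sas_l <- gs(lig)
      dpol <- pol_c - c(pol_r, pol_l)
      dsas <- gamma * (sas_c - c(sas_r, sas_l))
      per_atom <- per_atom + dpol + dsas
    }
    contrib[fi, ] <- per_atom
    total[fi] <- sum(per_atom)
  }
  by_res <- tapply(colMeans(contrib), labels, sum)
  # keep receptor-residue order of first appearance, ligand last
  ord <- unique(labels)
  out <- data.frame(residue = ord, contribution = as.numeric(by_res[ord]))
  g_total <- mean(total)
  residual <- g_total - sum(out$contribution)
  structure(out, G_binding = g_total, closure_residual = residual,
            class = c("residue_decomposition", "data.frame"))
}

#' Component-wise difference of two binding breakdowns
#'
#' \eqn{\Delta G = G_{on} - G_{off}} per component with bootstrap standard
#' errors propagated in quadrature. Both breakdowns must have been computed
#' with identical settings.
#'
#' @param field_on,field_off \code{binding_breakdown}s.
#' @return A list with per-component differences \code{delta} and propagated
#'   \code{se}.
#' @export
delta_g <- function(field_on, field_off) {
  if (!identical(field_on$settings, field_off$settings))
    stop("binding breakdowns were computed with different settings")
  comps <- c("E_vdw", "E_elec", "G_polar", "G_nonpolar", "G_binding")
  delta <- vapply(comps, function(k) field_on[[k]] - field_off[[k]], 0)
  se <- sqrt(field_on$se_bootstrap[comps]^2 + field_off$se_bootstrap[comps]^2)
  list(delta = delta, se = se)
}
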