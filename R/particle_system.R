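#' Construct a particle system
#'
#' The central container for a molecular system: coordinates, velocities,
#' masses, partial charges, labels, named atom groups, bonded terms and
#' Lennard-Jones parameters, in MD units (nm, ps, u, e, kJ/mol). Atom indices
#' are 1-based everywhere (bonds, angles, groups); PDB serial numbers, when a
#' system comes from a structure file, survive only as labels.
#'
#' @param positions numeric n x 3 matrix, nm.
#' @param masses numeric vector length n, u; all > 0.
#' @param box_edge cubic box edge, nm; > 0.
#' @param charges numeric vector length n, e. Default 0.
#' @param velocities numeric n x 3 matrix, nm/ps. Default 0.
#' @param atom_names,residue_names character vectors length n.
#' @param residue_ids integer vector length n.
#' @param groups named list of integer index vectors (e.g. \code{ligand},
#'   \code{receptor}, \code{pocket}).
#' @param bonds data.frame with columns \code{i, j, kb, r0}: harmonic bonds
#'   \eqn{V = kb/2 (r - r0)^2}, kb in kJ/mol/nm^2.
#' @param angles data.frame with columns \code{i, j, k, ka, theta0}: harmonic
#'   angles around the central atom \code{j}, ka in kJ/mol/rad^2, theta0 rad.
#' @param pairs_dw data.frame with columns \code{i, j, a4, r0, b, d}: quartic
#'   double-well pair terms \eqn{V(z) = a4 (z^4 - 4/3 (b+d) z^3 + 2 b d z^2)}
#'   with \eqn{z = r - r0}; minima at \eqn{z = 0} and \eqn{z = d}, barrier at
#'   \eqn{z = b} (0 < b < d). Used for bistable (switchable) contacts.
#' @param lj_sigma,lj_eps per-atom Lennard-Jones parameters, nm and kJ/mol;
#'   pair parameters by Lorentz-Berthelot combination. Default 0 (no LJ).
#' @param radii per-atom radii for implicit-solvent terms (PB dielectric
#'   boundary, SASA), nm. Defaults to \code{2^(1/6)/2 * lj_sigma}.
#'
#' @return An object of class \code{particle_system}.
#' @export
particle_system <- function(positions, masses, box_edge,
                            charges = NULL, velocities = NULL,
                            atom_names = NULL, residue_ids = NULL,
                            residue_names = NULL, groups = list(),
                            bonds = NULL, angles = NULL, pairs_dw = NULL,
                            lj_sigma = NULL, lj_eps = NULL, radii = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must be an n x 3 matrix")
  n <- nrow(positions)
  if (length(masses) != n) stop("masses must have length n_atoms")
  if (any(!is.finite(masses)) || any(masses <= 0)) stop("masses must be > 0")
  if (!is.numeric(box_edge) || length(box_edge) != 1L || box_edge <= 0)
    stop("box_edge must be a single positive number (nm)")

  if (is.null(charges)) charges <- numeric(n)
  if (is.null(velocities)) velocities <- matrix(0, n, 3L)
  velocities <- as.matrix(velocities)
  if (is.null(atom_names)) atom_names <- paste0("X", seq_len(n))
  if (is.null(residue_ids)) residue_ids <- rep(1L, n)
  if (is.null(residue_names)) residue_names <- rep("UNK", n)
  if (is.null(lj_sigma)) lj_sigma <- numeric(n)
  if (is.null(lj_eps)) lj_eps <- numeric(n)
  if (is.null(radii)) radii <- 2^(1/6) / 2 * lj_sigma

  per_atom_len <- c(length(charges), nrow(velocities), length(atom_names),
                    length(residue_ids), length(residue_names),
                    length(lj_sigma), length(lj_eps), length(radii))
  if (any(per_atom_len != n))
    stop("all per-atom arrays must have identical length n_atoms = ", n)
  if (any(lj_sigma < 0) || any(lj_eps < 0)) stop("lj_sigma and lj_eps must be >= 0")

  groups <- lapply(groups, as.integer)
  for (g in names(groups)) {
    idx <- groups[[g]]
    if (length(idx) && (any(idx < 1L) || any(idx > n)))
      stop("group '", g, "' has atom indices outside 1..", n)
  }

  chk_terms <- function(df, cols, what) {
    if (is.null(df)) return(df[0, ])
    df <- as.data.frame(df)
    if (!all(cols %in% names(df)))
      stop(what, " must have columns ", paste(cols, collapse = ", "))
    idx_cols <- intersect(c("i", "j", "k"), cols)
    for (cc in idx_cols) {
      df[[cc]] <- as.integer(df[[cc]])
      if (any(df[[cc]] < 1L) || any(df[[cc]] > n))
        stop(what, " indices out of range")
    }
    if (nrow(df)) {
      idx <- as.matrix(df[idx_cols])
      if (any(apply(idx, 1L, function(r) anyDuplicated(r) > 0L)))
        stop(what, " indices must be distinct within a term")
    }
    df
  }
  empty_bonds  <- data.frame(i = integer(), j = integer(),
                             kb = numeric(), r0 = numeric())
  empty_angles <- data.frame(i = integer(), j = integer(), k = integer(),
                             ka = numeric(), theta0 = numeric())
  empty_dw <- data.frame(i = integer(), j = integer(), a4 = numeric(),
                         r0 = numeric(), b = numeric(), d = numeric())
  bonds    <- if (is.null(bonds)) empty_bonds else
    chk_terms(bonds, c("i", "j", "kb", "r0"), "bonds")
  angles   <- if (is.null(angles)) empty_angles else
    chk_terms(angles, c("i", "j", "k", "ka", "theta0"), "angles")
  pairs_dw <- if (is.null(pairs_dw)) empty_dw else
    chk_terms(pairs_dw, c("i", "j", "a4", "r0", "b", "d"), "pairs_dw")

  structure(list(
    n_atoms = n,
    positions = unname(positions),
    velocities = unname(velocities),
    masses = as.numeric(masses),
    charges = as.numeric(charges),
    atom_names = as.character(atom_names),
    residue_ids = as.integer(residue_ids),
    residue_names = as.character(residue_names),
    groups = groups,
    bonds = bonds,
    angles = angles,
    pairs_dw = pairs_dw,
    lj_sigma = as.numeric(lj_sigma),
    lj_eps = as.numeric(lj_eps),
    radii = as.numeric(radii),
    box_edge = as.numeric(box_edge)
  ), class = "particle_system")
}

#' @export
print.particle_system <- function(x, ...) {
  cat("<particle_system> ", x$n_atoms, " atoms, box ", x$box_edge, " nm\n",
      sep = "")
  cat("  residues: ", length(unique(paste(x$residue_names, x$residue_ids))),
      "; bonds: ", nrow(x$bonds), "; angles: ", nrow(x$angles),
      "; double-well pairs: ", nrow(x$pairs_dw), "\n", sep = "")
  if (length(x$groups))
    cat("  groups: ", paste(sprintf("%s(%d)", names(x$groups),
                                    vapply(x$groups, length, 1L)),
                            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Atom indices of the named residues
#'
#' @param system a \code{particle_system}.
#' @param residue_names character vector of residue names (e.g. "GLN");
#'   \code{NULL} matches any name.
#' @param residue_ids integer vector of residue ids; \code{NULL} matches any.
#' @return Integer vector of 1-based atom indices.
#' @export
select_residues <- function(system, residue_names = NULL, residue_ids = NULL) {
  keep <- rep(TRUE, system$n_atoms)
  if (!is.null(residue_names)) keep <- keep & system$residue_names %in% residue_names
  if (!is.null(residue_ids)) keep <- keep & system$residue_ids %in% residue_ids
  which(keep)
}

# 1-2 (bond, double-well) and 1-3 (angle) exclusions for nonbonded terms,
# returned as a 2-column integer matrix with i < j.
nonbonded_exclusions <- function(system) {
  ex <- rbind(
    as.matrix(system$bonds[, c("i", "j")]),
    as.matrix(system$pairs_dw[, c("i", "j")]),
    as.matrix(system$angles[, c("i", "k")])
  )
  if (!nrow(ex)) return(matrix(integer(), 0L, 2L))
  ex <- t(apply(ex, 1L, sort))
  unique(ex)
}
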