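#' Read a PDB structure into a particle system
#'
#' Parses ATOM/HETATM records (via \pkg{bio3d}), converts coordinates from
#' Angstrom to nm, and builds a \code{particle_system}. Charges,
#' Lennard-Jones parameters and masses are not carried by PDB: charges and LJ
#' default to zero and masses to a per-element lookup (1 u when the element
#' is unrecognized), to be assigned afterwards by a generator or a parameter
#' table.
#'
#' @param path path to a PDB file.
#' @param box_edge cubic box edge to assign, nm. Default 8.0.
#' @return A \code{particle_system}.
#' @export
read_structure <- function(path, box_edge = 8.0) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", raw)
  if (!any(rec))
    stop("no ATOM/HETATM records in ", path, ": empty or not a PDB file")
  # coordinate fields must parse as numbers; report the offending line
  for (ln in which(rec)) {
    line <- raw[ln]
    if (nchar(line) < 54)
      stop("malformed ATOM record at line ", ln, ": missing coordinates")
    xyz <- suppressWarnings(as.numeric(c(substr(line, 31, 38),
                                         substr(line, 39, 46),
                                         substr(line, 47, 54))))
    if (any(is.na(xyz)))
      stop("malformed ATOM record at line ", ln, ": non-numeric coordinates")
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  masses <- element_mass(at$elesy, at$elety)
  particle_system(
    positions = cbind(at$x, at$y, at$z) / 10,   # Angstrom -> nm
    masses = masses,
    box_edge = box_edge,
    atom_names = at$elety,
    residue_ids = at$resno,
    residue_names = at$resid
  )
}

element_mass <- function(element, atom_name) {
  tbl <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
           P = 30.974, K = 39.098, CL = 35.45, NA. = 22.99, X = 1)
  el <- toupper(trimws(element))
  bad <- is.na(el) | el == "" | !(el %in% names(tbl))
  # fall back on the first letter of the atom name
  el[bad] <- substr(toupper(trimws(atom_name[bad])), 1L, 1L)
  m <- tbl[el]
  m[is.na(m)] <- 1
  unname(m)
}

#' Write a particle system as a PDB file
#'
#' Coordinates are converted nm to Angstrom. Intended for the synthetic
#' generators' output; occupancy/B-factor are written as zeros.
#'
#' @param system a \code{particle_system}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_structure <- function(system, path) {
  xyz <- as.vector(t(system$positions * 10))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = system$residue_ids,
                   resid = system$residue_names,
                   elety = system$atom_names,
                   chain = rep("A", system$n_atoms))
  invisible(path)
}
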