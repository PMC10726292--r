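#' Geometric interaction criteria
#'
#' Standard MD-community geometric definitions, all configurable: a hydrogen
#' bond is a donor-acceptor pair with heavy-atom distance <= \code{d_max} and
#' D-H...A angle >= \code{angle_min}; a hydrophobic contact is an
#' apolar-carbon pair within \code{d_hydro}.
#'
#' @param d_max donor-acceptor distance cutoff, nm. Default 0.35.
#' @param angle_min minimum D-H...A angle, degrees. Default 150.
#' @param d_hydro apolar carbon-carbon contact cutoff, nm. Default 0.40.
#' @param stable_threshold occupancy at or above which an interaction counts
#'   as stable. Default 0.5.
#' @return A list of class \code{hbond_criteria}.
#' @export
hbond_criteria <- function(d_max = 0.35, angle_min = 150, d_hydro = 0.40,
                           stable_threshold = 0.5) {
  if (d_max <= 0 || d_hydro <= 0) stop("distance cutoffs must be > 0")
  if (angle_min < 0 || angle_min > 180) stop("angle_min must be in [0, 180]")
  if (stable_threshold <= 0 || stable_threshold > 1)
    stop("stable_threshold must be in (0, 1]")
  structure(list(d_max = d_max, angle_min = angle_min, d_hydro = d_hydro,
                 stable_threshold = stable_threshold),
            class = "hbond_criteria")
}

# hydrogen attached to each donor heavy atom, from the bond list
donor_hydrogens <- function(system, donors) {
  b <- system$bonds
  is_h <- startsWith(system$atom_names, "H")
  hyd <- integer(length(donors))
  for (m in seq_along(donors)) {
    d <- donors[m]
    partners <- c(b$j[b$i == d], b$i[b$j == d])
    hs <- partners[is_h[partners]]
    if (!length(hs))
      stop("configuration error: donor atom ", d, " (",
           system$atom_names[d], ") has no bonded hydrogen")
    hyd[m] <- hs[1L]
  }
  hyd
}

res_label <- function(system, idx) {
  paste0(system$residue_names[idx], system$residue_ids[idx])
}

mi_dist <- function(p1, p2, box) {
  d <- p1 - p2
  d <- d - box * round(d / box)
  sqrt(sum(d^2))
}

#' Detect hydrogen bonds in one configuration
#'
#' All donor-acceptor pairs with heavy-atom distance <= \code{d_max} and
#' D-H...A angle (at the hydrogen) >= \code{angle_min}, ordered by (donor
#' index, acceptor index). Minimum-image distances are used.
#'
#' @param system a \code{particle_system} holding the frame's coordinates.
#' @param donors integer indices of donor heavy atoms; each must have a
#'   bonded hydrogen in the topology.
#' @param acceptors integer indices of acceptor atoms.
#' @param criteria an \code{\link{hbond_criteria}}.
#' @return data.frame with columns donor_atom, hydrogen_atom, acceptor_atom,
#'   donor_residue, acceptor_residue, distance (nm), angle (degrees).
#' @export
detect_hbonds <- function(system, donors, acceptors,
                          criteria = hbond_criteria()) {
  donors <- sort(as.integer(donors))
  acceptors <- sort(as.integer(acceptors))
  hyd <- donor_hydrogens(system, donors)
  box <- system$box_edge
  out <- list()
  for (m in seq_along(donors)) {
    d <- donors[m]; h <- hyd[m]
    for (a in acceptors) {
      if (a == d || a == h) next
      dist_da <- mi_dist(system$positions[d, ], system$positions[a, ], box)
      if (dist_da > criteria$d_max) next
      v1 <- system$positions[d, ] - system$positions[h, ]
      v2 <- system$positions[a, ] - system$positions[h, ]
      v1 <- v1 - box * round(v1 / box); v2 <- v2 - box * round(v2 / box)
      cs <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      ang <- acos(max(-1, min(1, cs))) * 180 / pi
      if (ang < criteria$angle_min) next
      out[[length(out) + 1L]] <- data.frame(
        donor_atom = d, hydrogen_atom = h, acceptor_atom = a,
        donor_residue = res_label(system, d),
        acceptor_residue = res_label(system, a),
        distance = dist_da, angle = ang)
    }
  }
  if (!length(out))
    return(data.frame(donor_atom = integer(), hydrogen_atom = integer(),
                      acceptor_atom = integer(), donor_residue = character(),
                      acceptor_residue = character(), distance = numeric(),
                      angle = numeric()))
  do.call(rbind, out)
}

system_at_frame <- function(traj, f) {
  sys <- traj$topology
  p <- traj$positions[f, , , drop = FALSE]; dim(p) <- c(sys$n_atoms, 3L)
  sys$positions <- p
  sys
}

#' Hydrogen-bond occupancy over a trajectory window
#'
#' For each unique directed (donor atom, acceptor atom) pair detected in at
#' least one frame, the fraction of window frames in which the bond satisfies
#' the criteria. Pairs never detected are absent from the table (not rows
#' with occupancy 0).
#'
#' @param traj an \code{md_trajectory}.
#' @param donors,acceptors atom indices (see \code{\link{detect_hbonds}}).
#' @param criteria an \code{\link{hbond_criteria}}.
#' @param window integer frame indices; default all frames.
#' @return A \code{contact_table}: data.frame(id, type, donor_residue,
#'   acceptor_residue, occupancy) with the criteria and window attached as
#'   attributes.
#' @export
hbond_occupancy <- function(traj, donors, acceptors,
                            criteria = hbond_criteria(), window = NULL) {
  window <- check_window(traj, window)
  counts <- new.env(parent = emptyenv())
  meta <- new.env(parent = emptyenv())
  for (f in window) {
    hb <- detect_hbonds(system_at_frame(traj, f), donors, acceptors, criteria)
    if (!nrow(hb)) next
    ids <- sprintf("hbond:%s.%d>%s.%d", hb$donor_residue, hb$donor_atom,
                   hb$acceptor_residue, hb$acceptor_atom)
    for (r in seq_along(ids)) {
      id <- ids[r]
      counts[[id]] <- (if (is.null(counts[[id]])) 0L else counts[[id]]) + 1L
      meta[[id]] <- c(hb$donor_residue[r], hb$acceptor_residue[r])
    }
  }
  ids <- sort(ls(counts))
  tab <- data.frame(
    id = ids, type = rep("hbond", length(ids)),
    donor_residue = vapply(ids, function(i) meta[[i]][1], ""),
    acceptor_residue = vapply(ids, function(i) meta[[i]][2], ""),
    occupancy = vapply(ids, function(i) counts[[i]], 0L) / length(window),
    row.names = NULL)
  as_contact_table(tab, criteria, window)
}

as_contact_table <- function(tab, criteria, window) {
  structure(tab, criteria = criteria, window = range(window),
            class = c("contact_table", "data.frame"))
}

check_window <- function(traj, window) {
  nf <- length(traj$times)
  if (is.null(window)) window <- seq_len(nf)
  window <- as.integer(window)
  if (!length(window)) stop("empty analysis window")
  if (any(window < 1L) || any(window > nf))
    stop("window frames outside 1..", nf)
  window
}

#' Frames of the final fraction of a trajectory
#'
#' The default analysis window mirrors post-equilibration sampling: the last
#' \code{frac} of the frames.
#'
#' @param traj an \code{md_trajectory}.
#' @param frac fraction in (0, 1]. Default 0.2.
#' @return Integer frame indices.
#' @export
final_window_frames <- function(traj, frac = 0.2) {
  nf <- length(traj$times)
  seq.int(max(1L, nf - ceiling(frac * nf) + 1L), nf)
}

#' Hydrophobic residue-pair contacts over a trajectory window
#'
#' A residue pair is in contact in a frame when any of its apolar carbons
#' are within \code{d_hydro}. Apolar carbons default to atoms whose name
#' starts with "C" and whose partial charge magnitude is below 0.25 e.
#'
#' @param traj an \code{md_trajectory}.
#' @param criteria an \code{\link{hbond_criteria}}.
#' @param apolar integer atom indices to treat as apolar; default inferred.
#' @param window integer frame indices; default all frames.
#' @return A \code{contact_table} with type \code{"hydrophobic"}.
#' @export
hydrophobic_contacts <- function(traj, criteria = hbond_criteria(),
                                 apolar = NULL, window = NULL) {
  window <- check_window(traj, window)
  sys <- traj$topology
  if (is.null(apolar))
    apolar <- which(startsWith(sys$atom_names, "C") & abs(sys$charges) < 0.25)
  apolar <- as.integer(apolar)
  if (length(apolar) < 2L)
    return(as_contact_table(
      data.frame(id = character(), type = character(),
                 donor_residue = character(), acceptor_residue = character(),
                 occupancy = numeric()), criteria, window))
  res_a <- res_label(sys, apolar)
  # candidate apolar pairs in different residues
  cmb <- utils::combn(seq_along(apolar), 2L)
  keep <- res_a[cmb[1, ]] != res_a[cmb[2, ]]
  cmb <- cmb[, keep, drop = FALSE]
  pair_res <- apply(rbind(res_a[cmb[1, ]], res_a[cmb[2, ]]), 2L,
                    function(x) paste(sort(x), collapse = "~"))
  counts <- new.env(parent = emptyenv())
  box <- sys$box_edge
  for (f in window) {
    p <- traj$positions[f, , , drop = FALSE]; dim(p) <- c(sys$n_atoms, 3L)
    d <- p[apolar[cmb[1, ]], , drop = FALSE] - p[apolar[cmb[2, ]], , drop = FALSE]
    d <- d - box * round(d / box)
    close <- sqrt(rowSums(d^2)) <= criteria$d_hydro
    for (pr in unique(pair_res[close])) {
      id <- paste0("hydro:", pr)
      counts[[id]] <- (if (is.null(counts[[id]])) 0L else counts[[id]]) + 1L
    }
  }
  ids <- sort(ls(counts))
  res12 <- do.call(rbind, strsplit(sub("^hydro:", "", ids), "~", fixed = TRUE))
  tab <- data.frame(
    id = ids, type = rep("hydrophobic", length(ids)),
    donor_residue = if (length(ids)) res12[, 1] else character(),
    acceptor_residue = if (length(ids)) res12[, 2] else character(),
    occupancy = vapply(ids, function(i) counts[[i]], 0L) / length(window),
    row.names = NULL)
  as_contact_table(tab, criteria, window)
}

#' Stable interactions of a contact table
#'
#' @param table a \code{contact_table}.
#' @param threshold occupancy threshold in (0, 1]; ids with occupancy >=
#'   threshold are returned. Default: the table's criteria
#'   \code{stable_threshold}.
#' @return Character vector of interaction ids.
#' @export
stable_set <- function(table, threshold = NULL) {
  if (is.null(threshold)) threshold <- attr(table, "criteria")$stable_threshold
  if (is.null(threshold)) threshold <- 0.5
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  sort(table$id[table$occupancy >= threshold])
}

#' Field-on versus field-off network difference
#'
#' Set differences of the stable interaction sets of two contact tables
#' built with identical criteria.
#'
#' @param before,after \code{contact_table}s (e.g. field-off / field-on).
#' @param threshold stable-occupancy threshold; default from criteria.
#' @return List with \code{added}, \code{removed}, \code{retained} id vectors.
#' @export
network_diff <- function(before, after, threshold = NULL) {
  cb <- attr(before, "criteria"); ca <- attr(after, "criteria")
  if (!identical(unclass(cb), unclass(ca)))
    stop("contact tables were built with different criteria")
  sb <- stable_set(before, threshold)
  sa <- stable_set(after, threshold)
  list(added = setdiff(sa, sb), removed = setdiff(sb, sa),
       retained = intersect(sb, sa))
}
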