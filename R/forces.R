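engine_args <- function(system) {
  list(
    pos = system$positions, vel = system$velocities,
    mass = system$masses, charge = system$charges,
    sigma = system$lj_sigma, epsv = system$lj_eps,
    box = system$box_edge,
    bonds_idx = as.matrix(system$bonds[, c("i", "j"), drop = FALSE]),
    bonds_par = as.matrix(system$bonds[, c("kb", "r0"), drop = FALSE]),
    ang_idx = as.matrix(system$angles[, c("i", "j", "k"), drop = FALSE]),
    ang_par = as.matrix(system$angles[, c("ka", "theta0"), drop = FALSE]),
    dw_idx = as.matrix(system$pairs_dw[, c("i", "j"), drop = FALSE]),
    dw_par = as.matrix(system$pairs_dw[, c("a4", "r0", "b", "d"), drop = FALSE]),
    excl = nonbonded_exclusions(system)
  )
}

fix_int_matrix <- function(m) {
  storage.mode(m) <- "integer"
  if (!nrow(m)) dim(m) <- c(0L, ncol(m))
  m
}

#' Forces and potential energy of a configuration
#'
#' Evaluates harmonic bonds and angles, double-well pair terms,
#' Lennard-Jones and truncated Coulomb interactions (minimum-image periodic
#' boundaries, shared real-space cutoff), and, when a field is given, the
#' oscillating-field force \eqn{F_i = q_i E(t)}. Forces are the exact
#' negative gradient of the reported potential; the field's bookkeeping
#' energy \eqn{-\sum_i q_i E(t)\cdot x_i} is reported as the
#' \code{field_coupling} component.
#'
#' @param system a \code{particle_system}.
#' @param config a \code{sim_config} (supplies the cutoff).
#' @param field optional \code{field_spec}.
#' @param t time at which the field is evaluated, ps.
#' @return A list of class \code{force_report}: \code{forces} (n x 3,
#'   kJ/mol/nm), \code{potential_energy} (kJ/mol), and \code{components}
#'   (named numeric: bond, angle, pair_dw, lj, coulomb, field_coupling).
#' @export
compute_forces <- function(system, config, field = NULL, t = 0) {
  validate_config_for_system(config, system)
  a <- engine_args(system)
  use_field <- !is.null(field)
  res <- .cpp_compute_forces(
    a$pos, a$vel, a$mass, a$charge, a$sigma, a$epsv, a$box,
    fix_int_matrix(a$bonds_idx), a$bonds_par,
    fix_int_matrix(a$ang_idx), a$ang_par,
    fix_int_matrix(a$dw_idx), a$dw_par,
    fix_int_matrix(a$excl), config$cutoff,
    use_field,
    if (use_field) field$amplitude else 0,
    if (use_field) field$frequency else 0,
    if (use_field) field$phase else 0,
    if (use_field) field$direction else c(0, 0, 1),
    t)
  structure(res, class = "force_report")
}

#' @export
print.force_report <- function(x, ...) {
  cat("<force_report> potential", format(x$potential_energy), "kJ/mol\n")
  print(round(x$components, 6))
  invisible(x)
}

#' Kinetic energy and instantaneous temperature
#'
#' \eqn{KE = \sum_i m_i v_i^2 / 2} in kJ/mol; kinetic temperature
#' \eqn{T = 2 KE / (3 N k_B)} (no constrained degrees of freedom).
#'
#' @param system a \code{particle_system}.
#' @return Named numeric vector with \code{kinetic} (kJ/mol) and
#'   \code{temperature} (K).
#' @export
kinetic_energy <- function(system) {
  ke <- 0.5 * sum(system$masses * rowSums(system$velocities^2))
  c(kinetic = ke,
    temperature = 2 * ke / (3 * system$n_atoms * md_constants$kB))
}
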