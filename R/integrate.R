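#' Run molecular dynamics
#'
#' Velocity-Verlet integration, optionally thermostatted with a Langevin
#' (BAOAB-splitting) scheme that reduces exactly to velocity Verlet at zero
#' friction, under periodic minimum-image boundaries and, optionally, an
#' oscillating electric field acting on the partial charges. Identical seeds
#' produce bitwise-identical trajectories; thermostat noise is drawn from one
#' seeded generator in fixed atom order.
#'
#' @param system a \code{particle_system} (initial positions/velocities).
#' @param config a \code{sim_config}; \code{config$n_steps} steps of
#'   \code{config$timestep} ps are taken and every
#'   \code{config$sample_every}-th step (plus the initial state) is recorded.
#' @param field optional \code{field_spec}; \code{NULL} for field-free runs.
#' @param duration optional run length in ps; overrides \code{config$n_steps}.
#' @return An \code{md_trajectory} with velocities, plus per-frame
#'   \code{potential} and \code{kinetic} energies (kJ/mol) attached as
#'   attributes \code{"potential"} and \code{"kinetic"}.
#' @examples
#' sys <- make_harmonic_probe(f0 = 10, mass = 10, charge = 0.5)
#' cfg <- sim_config(timestep = 2e-4, n_steps = 5000, sample_every = 5)
#' traj <- integrate_md(sys, cfg)
#' @export
integrate_md <- function(system, config, field = NULL, duration = NULL) {
  validate_config_for_system(config, system)
  n_steps <- config$n_steps
  if (!is.null(duration)) {
    if (duration <= 0) stop("duration must be > 0 (ps)")
    n_steps <- as.integer(round(duration / config$timestep))
  }
  # warn if the timestep underresolves the driving frequency
  if (!is.null(field) && field$frequency > 0 &&
      config$timestep > 1 / (20 * field$frequency))
    warning("timestep ", config$timestep, " ps resolves the ",
            field$frequency, " THz drive with fewer than 20 steps/period")
  a <- engine_args(system)
  use_field <- !is.null(field)
  res <- .cpp_integrate(
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
    config$timestep, n_steps,
    config$thermostat == "langevin", config$friction,
    config$temperature, config$seed, config$sample_every)
  traj <- trajectory(system, res$times, res$positions, res$velocities)
  attr(traj, "potential") <- res$potential
  attr(traj, "kinetic") <- res$kinetic
  traj
}

#' Final-frame system state of a trajectory
#'
#' @param traj an \code{md_trajectory}.
#' @return The topology \code{particle_system} with positions and velocities
#'   replaced by the last frame's.
#' @export
final_state <- function(traj) {
  sys <- traj$topology
  nf <- length(traj$times)
  p <- traj$positions[nf, , , drop = FALSE]; dim(p) <- c(sys$n_atoms, 3L)
  sys$positions <- p
  if (!is.null(traj$velocities)) {
    v <- traj$velocities[nf, , , drop = FALSE]; dim(v) <- c(sys$n_atoms, 3L)
    sys$velocities <- v
  }
  sys
}

#' Draw Maxwell-Boltzmann velocities
#'
#' @param system a \code{particle_system}.
#' @param temperature K.
#' @param seed integer seed.
#' @return The system with velocities drawn from the Maxwell-Boltzmann
#'   distribution at \code{temperature}.
#' @export
thermalize <- function(system, temperature = 300, seed = 1L) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  sd_v <- sqrt(md_constants$kB * temperature / system$masses)
  system$velocities <- matrix(stats::rnorm(3L * system$n_atoms), ncol = 3L) * sd_v
  system
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
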