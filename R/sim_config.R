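#' Simulation settings
#'
#' Integration and sampling settings for \code{\link{integrate_md}}. Defaults
#' follow common MD practice for small implicit-solvent systems: 1 fs
#' timestep, 300 K, 1.0 nm real-space cutoff.
#'
#' @param timestep integration timestep, ps; > 0. Default 0.001 (1 fs).
#' @param n_steps number of integration steps.
#' @param temperature target temperature, K. Default 300.
#' @param thermostat \code{"none"} (NVE) or \code{"langevin"}.
#' @param friction Langevin friction, 1/ps. Default 1.0.
#' @param cutoff nonbonded cutoff, nm; must be <= box_edge/2 at run time.
#' @param electrostatics \code{"cutoff"} (minimum-image truncated Coulomb).
#'   An Ewald mode is not provided at desk scale; requesting \code{"ewald"}
#'   is an error.
#' @param seed integer seed; fully determines all stochastic draws.
#' @param sample_every store every this-many steps in the returned trajectory.
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(timestep = 0.001, n_steps = 1000L, temperature = 300,
                       thermostat = c("none", "langevin"), friction = 1.0,
                       cutoff = 1.0, electrostatics = c("cutoff", "ewald"),
                       seed = 1L, sample_every = 1L) {
  thermostat <- match.arg(thermostat)
  electrostatics <- match.arg(electrostatics)
  if (electrostatics == "ewald")
    stop("electrostatics = 'ewald' is not available; use 'cutoff'")
  if (timestep <= 0) stop("timestep must be > 0 (ps)")
  if (n_steps < 1L) stop("n_steps must be >= 1")
  if (friction < 0) stop("friction must be >= 0 (1/ps)")
  if (cutoff <= 0) stop("cutoff must be > 0 (nm)")
  if (sample_every < 1L) stop("sample_every must be >= 1")
  structure(list(timestep = timestep, n_steps = as.integer(n_steps),
                 temperature = temperature, thermostat = thermostat,
                 friction = friction, cutoff = cutoff,
                 electrostatics = electrostatics, seed = as.integer(seed),
                 sample_every = as.integer(sample_every)),
            class = "sim_config")
}

validate_config_for_system <- function(config, system) {
  if (config$cutoff > system$box_edge / 2)
    stop("cutoff (", config$cutoff, " nm) exceeds box_edge/2 (",
         system$box_edge / 2, " nm): minimum image invalid")
  invisible(TRUE)
}
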