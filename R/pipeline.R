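#' Pipeline run configuration
#'
#' Bundles the input source, simulation settings, field, analysis settings,
#' output directory and global seed for \code{\link{run_pipeline}}. Field
#' defaults are the study conditions: nu = 34.5 THz, A = 0.5 V/nm,
#' u = (0,0,1), phi = 0.
#'
#' @param input list: \code{kind} ("host_guest", "harmonic_probe" or
#'   "structure") plus generator parameters or a \code{path}.
#' @param sim list: \code{timestep} (ps), \code{equil_ps}, \code{prod_ps},
#'   \code{temperature}, \code{friction} (1/ps), \code{cutoff} (nm),
#'   \code{sample_every} (steps).
#' @param field list: \code{amplitude} (V/nm), \code{frequency} (THz),
#'   \code{direction}, \code{phase}.
#' @param analysis list: \code{contact_window_frac}, \code{contact_max_frames},
#'   \code{sampling_interval} (ps, binding), \code{n_boot},
#'   \code{pb} (args for \code{\link{polar_solvation}}), \code{np} (args for
#'   \code{\link{nonpolar_solvation}}), \code{spectrum_group}.
#' @param out_dir output directory (created).
#' @param seed global integer seed; together with the config it reproduces
#'   every numeric output exactly.
#' @param log_level "info" or "quiet".
#' @return A validated list of class \code{run_config}.
#' @export
run_config <- function(input = list(kind = "host_guest"),
                       sim = list(), field = list(), analysis = list(),
                       out_dir = tempfile("thzrun"), seed = 1L,
                       log_level = "info") {
  sim_def <- list(timestep = 2.5e-4, equil_ps = 4, prod_ps = 40,
                  temperature = 300, thermostat = "langevin", friction = 0.5,
                  cutoff = 2.0, sample_every = 10L)
  field_def <- list(amplitude = 0.5, frequency = 34.5,
                    direction = c(0, 0, 1), phase = 0)
  ana_def <- list(contact_window_frac = 0.2, contact_max_frames = 600L,
                  sampling_interval = 1.0, binding_window_frac = 0.5,
                  n_boot = 1000L,
                  pb = list(grid_spacing = 0.05), np = list(),
                  spectrum_group = NULL)
  cfg <- list(input = input,
              sim = utils::modifyList(sim_def, sim),
              field = utils::modifyList(field_def, field),
              analysis = utils::modifyList(ana_def, analysis),
              out_dir = out_dir, seed = as.integer(seed),
              log_level = log_level)
  if (is.null(cfg$input$kind) ||
      !cfg$input$kind %in% c("host_guest", "harmonic_probe", "structure"))
    stop("input$kind must be host_guest, harmonic_probe or structure")
  if (cfg$input$kind == "structure" && is.null(cfg$input$path))
    stop("input$kind 'structure' needs input$path")
  with(cfg$sim, {
    if (timestep <= 0 || prod_ps <= 0) stop("timestep and prod_ps must be > 0")
  })
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose top-level keys match \code{\link{run_config}}
#'   arguments.
#' @return A \code{run_config}.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

# deterministic polynomial hash of the serialized configuration
config_hash <- function(cfg) {
  txt <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = 12)
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

plog <- function(cfg, ...) {
  if (!identical(cfg$log_level, "quiet"))
    message(format(Sys.time(), "[%H:%M:%S] "), ...)
}

pipeline_system <- function(cfg) {
  inp <- cfg$input
  if (inp$kind == "host_guest") {
    do.call(make_host_guest, c(
      inp[setdiff(names(inp), c("kind", "path"))], list(seed = cfg$seed)))
  } else if (inp$kind == "harmonic_probe") {
    do.call(make_harmonic_probe, inp[setdiff(names(inp), c("kind", "path"))])
  } else {
    read_structure(inp$path)
  }
}

stage_traj <- function(cfg, sys, name, field) {
  path <- file.path(cfg$out_dir, paste0(name, ".trj"))
  if (file.exists(path)) {
    plog(cfg, "stage ", name, ": cached")
    return(read_trajectory(path, sys))
  }
  plog(cfg, "stage ", name, ": simulating")
  scfg <- sim_config(timestep = cfg$sim$timestep,
                     n_steps = round(cfg$sim$prod_ps / cfg$sim$timestep),
                     temperature = cfg$sim$temperature,
                     thermostat = cfg$sim$thermostat,
                     friction = cfg$sim$friction,
                     cutoff = cfg$sim$cutoff, seed = cfg$seed,
                     sample_every = cfg$sim$sample_every)
  traj <- integrate_md(sys, scfg, field = field)
  write_trajectory(traj, path)
  traj
}

#' Run the full field-off / field-on analysis pipeline
#'
#' Stages: generate or read the system; thermalize and equilibrate
#' (field-off); run field-off and field-on production arms with common
#' random numbers; compute the group absorption spectrum from the field-off
#' arm; compute hydrogen-bond/hydrophobic occupancy tables and their network
#' difference; compute the MM-PBSA binding-energy difference (when the
#' system defines receptor and ligand groups). Completed stages are
#' checkpointed in \code{out_dir} and are not recomputed on resume (the
#' stored config hash must match).
#'
#' @param config a \code{\link{run_config}}.
#' @return A \code{run_report} list: per-stage status, file manifest,
#'   headline numbers, config hash. Also written as \code{report.json}.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  hfile <- file.path(cfg$out_dir, "config_hash.txt")
  if (file.exists(hfile) && !identical(readLines(hfile, 1L), hash))
    stop("out_dir holds checkpoints for a different configuration; ",
         "clear it or change out_dir")
  writeLines(hash, hfile)
  stages <- list()
  headline <- list()
  files <- character(0)

  # --- system --------------------------------------------------------------
  sys <- pipeline_system(cfg)
  validate_config_for_system(sim_config(cutoff = cfg$sim$cutoff), sys)
  pdb <- file.path(cfg$out_dir, "system.pdb")
  if (!file.exists(pdb)) {
    write_structure(sys, pdb)
    if (!is.null(attr(sys, "manifest")))
      write_manifest(sys, file.path(cfg$out_dir, "manifest.json"))
  }
  files <- c(files, pdb)
  stages$generate <- "ok"
  man <- attr(sys, "manifest")

  # --- equilibration (field off) ------------------------------------------
  eq_path <- file.path(cfg$out_dir, "equilibrated.trj")
  if (file.exists(eq_path)) {
    sys_eq <- final_state(read_trajectory(eq_path, sys))
  } else if (cfg$sim$equil_ps > 0) {
    plog(cfg, "stage equilibrate: ", cfg$sim$equil_ps, " ps")
    scfg <- sim_config(timestep = cfg$sim$timestep,
                       n_steps = round(cfg$sim$equil_ps / cfg$sim$timestep),
                       temperature = cfg$sim$temperature,
                       thermostat = "langevin", friction = cfg$sim$friction,
                       cutoff = cfg$sim$cutoff, seed = cfg$seed + 1000L,
                       sample_every = max(1L, round(cfg$sim$equil_ps /
                                                      cfg$sim$timestep / 10)))
    eq <- integrate_md(thermalize(sys, cfg$sim$temperature, cfg$seed), scfg)
    write_trajectory(eq, eq_path)
    sys_eq <- final_state(eq)
  } else if (cfg$sim$thermostat == "none") {
    # deterministic microcanonical run from the constructed state
    sys_eq <- sys
  } else {
    sys_eq <- thermalize(sys, cfg$sim$temperature, cfg$seed)
  }
  stages$equilibrate <- "ok"

  # --- production arms -----------------------------------------------------
  fs <- field_spec(cfg$field$amplitude, cfg$field$frequency,
                   cfg$field$direction, cfg$field$phase)
  traj_off <- stage_traj(cfg, sys_eq, "prod_off", field = NULL)
  traj_on <- stage_traj(cfg, sys_eq, "prod_on", field = fs)
  stages$simulate <- "ok"

  # --- spectrum ------------------------------------------------------------
  grp <- cfg$analysis$spectrum_group
  if (is.null(grp))
    grp <- if ("pocket" %in% names(sys$groups)) "pocket"
           else names(sys$groups)[1]
  spec <- absorption_spectrum(traj_off, grp)
  pk <- find_peak(spec)
  utils::write.csv(data.frame(frequency_THz = spec$frequencies,
                              absorption_au = spec$absorption),
                   file.path(cfg$out_dir, "spectrum.csv"), row.names = FALSE)
  headline$spectrum_peak_THz <- unname(pk["frequency"])
  headline$spectrum_group <- grp
  stages$spectrum <- "ok"

  # --- contact network -----------------------------------------------------
  if (all(c("donors", "acceptors") %in% names(sys$groups))) {
    win <- function(traj) {
      w <- final_window_frames(traj, cfg$analysis$contact_window_frac)
      if (length(w) > cfg$analysis$contact_max_frames)
        w <- w[unique(round(seq(1, length(w),
                                length.out = cfg$analysis$contact_max_frames)))]
      w
    }
    tab_off <- hbond_occupancy(traj_off, sys$groups$donors,
                               sys$groups$acceptors, window = win(traj_off))
    tab_on <- hbond_occupancy(traj_on, sys$groups$donors,
                              sys$groups$acceptors, window = win(traj_on))
    nd <- network_diff(tab_off, tab_on)
    jsonlite::write_json(
      list(added = nd$added, removed = nd$removed, retained = nd$retained,
           occupancy_off = tab_off, occupancy_on = tab_on),
      file.path(cfg$out_dir, "network_diff.json"), dataframe = "rows",
      pretty = TRUE)
    headline$stable_hbonds_off <- length(stable_set(tab_off))
    headline$stable_hbonds_on <- length(stable_set(tab_on))
    headline$hbonds_added <- nd$added
    headline$hbonds_removed <- nd$removed
    stages$contacts <- "ok"
  } else stages$contacts <- "skipped (no donor/acceptor groups)"

  # --- binding energy ------------------------------------------------------
  if (all(c("receptor", "ligand") %in% names(sys$groups))) {
    plog(cfg, "stage binding: MM-PBSA on both arms")
    bfe <- function(traj) binding_free_energy(
      traj, "receptor", "ligand",
      sampling_interval = cfg$analysis$sampling_interval,
      window = final_window_frames(traj, cfg$analysis$binding_window_frac),
      n_boot = cfg$analysis$n_boot, seed = cfg$seed,
      pb_args = cfg$analysis$pb, np_args = cfg$analysis$np)
    g_off <- bfe(traj_off)
    g_on <- bfe(traj_on)
    dg <- delta_g(g_on, g_off)
    headline$G_binding_off <- g_off$G_binding
    headline$G_binding_on <- g_on$G_binding
    headline$delta_G <- as.list(dg$delta)
    headline$delta_G_se <- as.list(unname(dg$se))
    jsonlite::write_json(
      list(field_off = unclass(g_off)[c("G_binding", "E_vdw", "E_elec",
                                        "G_polar", "G_nonpolar",
                                        "se_bootstrap", "n_frames")],
           field_on = unclass(g_on)[c("G_binding", "E_vdw", "E_elec",
                                      "G_polar", "G_nonpolar",
                                      "se_bootstrap", "n_frames")],
           delta = dg),
      file.path(cfg$out_dir, "binding.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    stages$binding <- "ok"
  } else stages$binding <- "skipped (no receptor/ligand groups)"

  report <- list(stages = stages, headline = headline,
                 files = list.files(cfg$out_dir),
                 config_hash = hash,
                 version = as.character(utils::packageVersion("thzbind")))
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 12, pretty = TRUE)
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> config", x$config_hash, "\n")
  for (s in names(x$stages)) cat(sprintf("  %-12s %s\n", s, x$stages[[s]]))
  h <- x$headline
  if (!is.null(h$spectrum_peak_THz))
    cat(sprintf("  peak: %.3f THz (%s)\n", h$spectrum_peak_THz,
                h$spectrum_group))
  if (!is.null(h$stable_hbonds_off))
    cat(sprintf("  stable H-bonds off/on: %d/%d; added: %s\n",
                h$stable_hbonds_off, h$stable_hbonds_on,
                paste(h$hbonds_added, collapse = ", ")))
  if (!is.null(h$delta_G))
    cat(sprintf("  delta G_binding: %.2f kJ/mol\n", h$delta_G$G_binding))
  invisible(x)
}

#' Field-intensity sweep of the binding-energy change
#'
#' One arm per amplitude against a shared field-off baseline, all with
#' common random numbers (identical seeds). Each arm applies the resonant
#' field for \code{cfg$sim$prod_ps} and then relaxes field-free for
#' \code{relax_ps}; the binding energy is computed over the final half of
#' the relaxation segment, so the sweep measures the persistent
#' (post-irradiation) change in binding rather than the driven steady
#' state.
#'
#' @param config a \code{\link{run_config}}.
#' @param amplitudes numeric vector of field amplitudes, V/nm; duplicates
#'   are an error.
#' @param relax_ps field-free relaxation run after each pulse, ps.
#' @return data.frame with one row per amplitude: the amplitude, each
#'   component of the binding-energy difference and its propagated
#'   bootstrap SE.
#' @export
intensity_sweep <- function(config, amplitudes, relax_ps = 20) {
  if (anyDuplicated(amplitudes)) stop("duplicate amplitudes")
  if (!length(amplitudes)) stop("need at least one amplitude")
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  sys <- pipeline_system(cfg)
  validate_config_for_system(sim_config(cutoff = cfg$sim$cutoff), sys)
  scfg_eq <- sim_config(timestep = cfg$sim$timestep,
                        n_steps = round(cfg$sim$equil_ps / cfg$sim$timestep),
                        temperature = cfg$sim$temperature,
                        thermostat = "langevin", friction = cfg$sim$friction,
                        cutoff = cfg$sim$cutoff, seed = cfg$seed + 1000L,
                        sample_every = 1000L)
  sys_eq <- final_state(integrate_md(
    thermalize(sys, cfg$sim$temperature, cfg$seed), scfg_eq))
  mk <- function(ps, seed) sim_config(
    timestep = cfg$sim$timestep, n_steps = round(ps / cfg$sim$timestep),
    temperature = cfg$sim$temperature, thermostat = cfg$sim$thermostat,
    friction = cfg$sim$friction, cutoff = cfg$sim$cutoff, seed = seed,
    sample_every = cfg$sim$sample_every)
  run_arm <- function(A) {
    fs <- if (A > 0) field_spec(A, cfg$field$frequency, cfg$field$direction,
                                cfg$field$phase) else NULL
    pulse <- integrate_md(sys_eq, mk(cfg$sim$prod_ps, cfg$seed), field = fs)
    integrate_md(final_state(pulse), mk(relax_ps, cfg$seed + 1L))
  }
  bfe <- function(traj) binding_free_energy(
    traj, "receptor", "ligand",
    sampling_interval = cfg$analysis$sampling_interval,
    window = final_window_frames(traj, 0.5),
    n_boot = cfg$analysis$n_boot, seed = cfg$seed,
    pb_args = cfg$analysis$pb, np_args = cfg$analysis$np)
  plog(cfg, "sweep baseline (field off)")
  g_off <- bfe(run_arm(0))
  rows <- lapply(amplitudes, function(A) {
    plog(cfg, "sweep arm A = ", A, " V/nm")
    dg <- if (A == 0) {
      list(delta = c(E_vdw = 0, E_elec = 0, G_polar = 0, G_nonpolar = 0,
                     G_binding = 0),
           se = sqrt(2) * g_off$se_bootstrap[c("E_vdw", "E_elec", "G_polar",
                                               "G_nonpolar", "G_binding")])
    } else delta_g(bfe(run_arm(A)), g_off)
    data.frame(amplitude = A,
               dG_total = dg$delta[["G_binding"]],
               dE_vdw = dg$delta[["E_vdw"]], dE_elec = dg$delta[["E_elec"]],
               dG_polar = dg$delta[["G_polar"]],
               dG_nonpolar = dg$delta[["G_nonpolar"]],
               se_total = dg$se[["G_binding"]])
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, file.path(cfg$out_dir, "intensity_sweep.csv"),
                   row.names = FALSE)
  out
}
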