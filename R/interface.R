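# Configuration-driven experiments: build -> minimize -> MD -> analyze,
# with reproducibility stamping (config hash + seed).

#' Run a configured experiment
#'
#' Executes the full pipeline described by a YAML configuration: build the
#' system (crystal builder, water-cluster builder, or an extended-XYZ
#' file), load the force field, attach shells, optionally declare an
#' embedded QM region with the Gaussian surrogate, initialise velocities,
#' equilibrate, run production MD and compute summary observables. All
#' outputs are stamped with the configuration hash and seed; the same
#' config + seed reproduce the same trajectory.
#'
#' Configuration sections (see `inst/configs/` for complete examples):
#' `system` (`source`: `crystal`|`water_cluster`|`xyz`, plus builder
#' arguments), `forcefield` (`preset`: `pmzhb`|`water`, or `file`),
#' `shells` (`attach`, `mass`), `embedding` (optional: `qm_molecule` or
#' `qm_atoms`, `mode`), `integrator` (`timestep`, `shell_mode`, `nsteps`,
#' `equilibration_steps`), `thermostats` (optional per-chain blocks
#' `nuclear`, `shell`, `surrogate` with `target`/`tau`/`links`/`enabled`;
#' the surrogate chain takes `target_ke_hartree`), `initialization`
#' (`temperature`, `seed`), `output` (`scalar_stride`, `frame_stride`,
#' `trajectory`).
#'
#' @param config path to a YAML file, or an equivalent nested list.
#' @param output_dir optional directory for `timeseries.tsv`,
#'   `trajectory.xyz` and `summary.yaml`.
#' @param seed overrides `initialization$seed`.
#' @return list with `run` (production `md_run`), `equilibration` (or
#'   NULL), `summary` (named list of scalars) and `sys`.
#' @export
run_experiment <- function(config, output_dir = NULL, seed = NULL) {
  cfg_path <- NULL
  if (is.character(config)) {
    cfg_path <- config
    config <- yaml::read_yaml(config)
  }
  need <- function(block, field, where) {
    if (is.null(block[[field]]))
      stop("config error at ", where, "$", field, ": required field missing")
    block[[field]]
  }
  sysc <- need(config, "system", "")
  ffc <- need(config, "forcefield", "")
  intc <- need(config, "integrator", "")
  init <- config$initialization %||% list()
  outc <- config$output %||% list()
  seed <- as.integer(seed %||% init$seed %||% 1)

  ff <- if (!is.null(ffc$file)) read_forcefield(ffc$file)
        else switch(need(ffc, "preset", "forcefield"),
                    pmzhb = load_pmzhb(), water = load_water_ff(),
                    stop("config error at forcefield$preset: unknown preset"))
  if (!is.null(ffc$ewald_accuracy)) ff$ewald_accuracy <- ffc$ewald_accuracy
  if (!is.null(ffc$exclusion_policy)) ff$exclusion_policy <- ffc$exclusion_policy

  shell_mass <- (config$shells %||% list())$mass %||% 0.2
  src <- need(sysc, "source", "system")
  sys <- switch(src,
    crystal = {
      s <- build_crystal(need(sysc, "polymorph", "system"),
                         sysc$replication %||% c(1, 1, 1), ff = ff)
      if (!isFALSE((config$shells %||% list())$attach))
        s <- attach_shells(s, ff, shell_mass = shell_mass)
      s
    },
    water_cluster = build_water_cluster(sysc$n_molecules %||% need(sysc, "n_molecules", "system"),
                                        seed = sysc$seed %||% seed, ff = ff,
                                        shell_mass = shell_mass),
    xyz = {
      s <- read_xyz(need(sysc, "path", "system"))
      detect_topology(s, cutoff = sysc$bond_cutoff %||% 2.0)
    },
    stop("config error at system$source: unknown source '", src, "'"))

  embc <- config$embedding
  if (!is.null(embc)) {
    qm <- embc$qm_atoms
    if (is.null(qm) && !is.null(embc$qm_molecule)) {
      if (is.null(sys$molecule)) stop("config error at embedding$qm_molecule: system has no molecule index")
      qm <- which(sys$molecule %in% embc$qm_molecule)
    }
    if (is.null(qm)) stop("config error at embedding$qm_atoms: QM region not specified")
    # rebuild shells so QM atoms carry none
    if (n_shells(sys) > 0) {
      keep <- !(sys$shells$owner %in% qm)
      sh <- sys$shells
      sys$charge[sh$owner[!keep]] <- sys$charge[sh$owner[!keep]] + sh$charge[!keep]
      sys$shells <- if (any(keep)) lapply(
        list(owner = sh$owner, pos = sh$pos, vel = sh$vel, mass = sh$mass,
             charge = sh$charge, k = sh$k),
        function(x) if (is.matrix(x)) x[keep, , drop = FALSE] else x[keep]) else NULL
    }
    sys <- make_embedding(sys, ff, qm_atoms = qm,
                          mode = embc$mode %||% "dynamical",
                          alpha = embc$alpha %||% 1.0,
                          dipole_mass = embc$dipole_mass %||% 0.05,
                          kernel_n = if (isFALSE(embc$kernel)) NULL else embc$kernel_n %||% 4)
  }

  cfgi <- integrator_config(
    timestep = intc$timestep %||% 0.2,
    shell_mode = intc$shell_mode %||% "extended_lagrangian",
    shell_mass = shell_mass,
    shell_force_tol = intc$shell_force_tol %||% 1e-4,
    seed = seed)

  temperature <- init$temperature %||% 300
  sys <- initialize_velocities(sys, temperature, seed = seed)

  chains <- list()
  thc <- config$thermostats %||% list()
  if (!is.null(thc$nuclear) && !isFALSE(thc$nuclear$enabled))
    chains$nuclear <- nhc_chain(thc$nuclear$target %||% temperature,
                                dof_count(sys), thc$nuclear$tau %||% 50,
                                thc$nuclear$links %||% 4)
  if (!is.null(thc$shell) && !isFALSE(thc$shell$enabled) && n_shells(sys) > 0)
    chains$shell <- nhc_chain(thc$shell$target %||% 1, 3L * n_shells(sys),
                              thc$shell$tau %||% 10, thc$shell$links %||% 4)
  if (!is.null(thc$surrogate) && !isFALSE(thc$surrogate$enabled) &&
      !is.null(sys$embedding)) {
    dof <- 3L * sum(sys$embedding$polarizable)
    ke_ev <- (thc$surrogate$target_ke_hartree %||% 7e-4) * .HARTREE
    chains$surrogate <- nhc_chain(ke_target_temperature(ke_ev, dof), dof,
                                  thc$surrogate$tau %||% 10,
                                  thc$surrogate$links %||% 4)
  }

  scalar_stride <- outc$scalar_stride %||% 10
  frame_stride <- outc$frame_stride %||% 0
  equil <- NULL
  n_eq <- intc$equilibration_steps %||% 0
  if (n_eq > 0) {
    equil <- run_md(sys, ff, cfgi, n_eq, chains = if (length(chains)) chains,
                    scalar_stride = scalar_stride)
    sys <- equil$sys
    chains <- equil$chains
  }
  run <- run_md(sys, ff, cfgi, need(intc, "nsteps", "integrator"),
                chains = if (length(chains)) chains,
                scalar_stride = scalar_stride, frame_stride = frame_stride,
                minimize_first = n_eq == 0)

  s <- run$series
  na <- n_atoms(run$sys)
  drift <- if (nrow(s) >= 3)
    energy_drift(s$time_fs, s$conserved_eV, na) else NULL
  summary <- list(
    seed = seed,
    config_hash = config_hash(config),
    package_version = as.character(utils::packageVersion("shellmd")),
    n_atoms = na, n_shells = n_shells(run$sys),
    timestep_fs = cfgi$timestep, nsteps = nrow(s) * scalar_stride,
    mean_T_phys_K = mean(s$T_phys_K),
    mean_T_s_K = if (all(is.na(s$T_s_K))) NA else mean(s$T_s_K, na.rm = TRUE),
    drift_au_per_atom_ps = if (!is.null(drift)) drift$au_per_atom_ps else NA,
    shell_mode = cfgi$shell_mode, shell_mass_amu = cfgi$shell_mass,
    exclusion_policy = ff$exclusion_policy,
    ewald_accuracy = ff$ewald_accuracy)
  if (all(c("Si", "O") %in% run$sys$species) && frame_stride > 0) {
    summary$mean_SiO_A <- mean_bond_length(run, c("Si", "O"), discard = 0)$mean
    summary$mean_OSiO_deg <- mean_angle(run, c("O", "Si", "O"), discard = 0)$mean
    summary$mean_SiOSi_deg <- mean_angle(run, c("Si", "O", "Si"), discard = 0)$mean
  }

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_timeseries(run$series, file.path(output_dir, "timeseries.tsv"))
    yaml::write_yaml(summary, file.path(output_dir, "summary.yaml"))
    if (isTRUE(outc$trajectory)) write_xyz(run$sys, file.path(output_dir, "final.xyz"))
  }
  list(run = run, equilibration = equil, summary = summary, sys = run$sys)
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  yaml::write_yaml(config, tf)
  unname(tools::md5sum(tf))
}
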