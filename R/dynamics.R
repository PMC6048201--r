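# Time propagation: velocity-Verlet NVE/NVT for cores + shells (extended
# Lagrangian), per-step shell minimization (adiabatic/Born-Oppenheimer
# mode), temperature diagnostics and the adiabaticity monitor.

#' Integrator configuration
#'
#' @param timestep MD timestep (fs). Default 0.2 fs; drift benchmarks use
#'   0.1 fs.
#' @param shell_mode `"extended_lagrangian"` (shells are dynamical variables
#'   with fictitious mass `shell_mass`) or `"minimize_each_step"`
#'   (shells relaxed to their minimum at every step, Born-Oppenheimer
#'   style).
#' @param shell_mass fictitious shell mass (amu), default 0.2, chosen so the
#'   core-shell spring frequency sits far above the physical phonon
#'   spectrum (adiabatic separation), with the [adiabaticity_monitor()] as
#'   the guard. When an embedded surrogate is propagated dynamically its
#'   internal variables play the same fictitious-mass role.
#' @param shell_force_tol maximum shell force (eV/A) for minimization.
#' @param max_minimizer_iterations conjugate-gradient iteration cap.
#' @param seed integer seed for stochastic initialisation.
#' @return list of class `integrator_config`.
#' @export
integrator_config <- function(timestep = 0.2,
                              shell_mode = c("extended_lagrangian",
                                             "minimize_each_step"),
                              shell_mass = 0.2, shell_force_tol = 1e-4,
                              max_minimizer_iterations = 500, seed = 1) {
  shell_mode <- match.arg(shell_mode)
  if (timestep <= 0) stop("timestep must be positive")
  if (shell_mode == "extended_lagrangian" && shell_mass <= 0)
    stop("shell mass must be positive in extended-Lagrangian mode")
  structure(list(timestep = timestep, shell_mode = shell_mode,
                 shell_mass = shell_mass, shell_force_tol = shell_force_tol,
                 max_minimizer_iterations = max_minimizer_iterations,
                 seed = as.integer(seed)),
            class = "integrator_config")
}

#' Physical and shell temperatures
#'
#' The physical temperature is the kinetic temperature of the core-shell
#' centre-of-mass motion, T_phys = (1/(N_f k_B)) sum_I Mbar_I |Sdot_I|^2,
#' and the shell temperature that of the relative core-shell motion,
#' T_s = (1/(3 n_s k_B)) sum_k mbar_k |sdot_k|^2. Keeping T_s near zero
#' while the nuclei are hot is the adiabatic-decoupling condition of the
#' extended-Lagrangian scheme.
#'
#' @param decomp a `pair_decomposition` (see [decompose_pairs()]).
#' @param nf number of nuclear degrees of freedom N_f.
#' @return temperature (K).
#' @export
physical_temperature <- function(decomp, nf) {
  if (nf <= 0) stop("N_f must be positive")
  twoK <- .MV2E * sum(decomp$pair_mass * rowSums(decomp$com_vel^2))
  twoK / (nf * .KB)
}

#' @rdname physical_temperature
#' @export
shell_temperature <- function(decomp) {
  ns <- length(decomp$red_mass)
  if (ns == 0) stop("shell temperature undefined: system has no shells")
  twoK <- .MV2E * sum(decomp$red_mass * rowSums(decomp$rel_vel^2))
  twoK / (3 * ns * .KB)
}

#' Initialise velocities
#'
#' Draws Maxwell-Boltzmann centre-of-mass velocities at the target
#' temperature with zero relative core-shell velocities (the cold-start
#' prescription for adiabatic dynamics), optionally removes the total
#' linear momentum, and rescales so the initial T_phys matches the target
#' exactly. Deterministic for a given seed.
#'
#' @param sys a `particle_system`.
#' @param temperature target T_phys (K).
#' @param seed integer seed.
#' @param remove_com remove total momentum; default: yes for open systems.
#' @return `sys` with velocities set.
#' @export
initialize_velocities <- function(sys, temperature, seed = 1,
                                  remove_com = NULL) {
  if (is.null(remove_com)) remove_com <- is.null(sys$cell)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  d <- decompose_pairs(sys)
  n <- n_atoms(sys)
  sigma <- sqrt(.KB * temperature / (d$pair_mass * .MV2E))
  d$com_vel <- matrix(stats::rnorm(3 * n), n, 3) * sigma
  d$rel_vel[] <- 0
  sys <- recompose_pairs(sys, d)
  if (remove_com) sys <- remove_com_momentum(sys)
  nf <- dof_count(sys, remove_com)
  t_now <- physical_temperature(decompose_pairs(sys), nf)
  if (t_now > 0) {
    fac <- sqrt(temperature / t_now)
    sys$vel <- sys$vel * fac
    if (n_shells(sys) > 0) sys$shells$vel <- sys$shells$vel * fac
  }
  sys
}

# single full-system force evaluation (MM kernel + optional embedding)
eval_forces <- function(sys, ftab, emb = NULL) {
  sh_pos <- if (n_shells(sys) > 0) sys$shells$pos else matrix(0, 0, 3)
  mm <- cpp_energy_forces(ftab, sys$pos, sh_pos)
  pot <- mm$bond + mm$angle + mm$lj + mm$coulomb + mm$spring
  f_core <- mm$f_core; f_shell <- mm$f_shell
  f_dip <- NULL; emb_report <- NULL
  if (!is.null(emb)) {
    if (emb$mode == "scf" && any(emb$polarizable)) emb <- surrogate_polarize(sys, emb)
    ee <- embedding_energy_force(sys, emb)
    pot <- pot + ee$energy
    f_core <- f_core + ee$f_core
    if (n_shells(sys) > 0) f_shell <- f_shell + ee$f_shell
    f_dip <- ee$f_dip
    emb_report <- ee$report
  }
  list(pot = pot, f_core = f_core, f_shell = f_shell, f_dip = f_dip,
       emb = emb, mm = mm, emb_report = emb_report)
}

#' Minimize shell positions at fixed cores
#'
#' Quasi-Newton (L-BFGS-B) minimization of the total energy over the shell
#' coordinates only, using the analytic shell forces as the exact gradient,
#' until the largest per-shell force norm falls below `tol`. Deterministic
#' given the starting point. If the system carries an embedding in SCF or
#' dynamical mode, the surrogate dipoles are relaxed self-consistently
#' alongside.
#'
#' @param sys a `particle_system` with shells.
#' @param ff a `forcefield`.
#' @param tol force tolerance (eV/A), default 1e-4.
#' @param max_iter iteration cap (error on non-convergence, reporting the
#'   residual).
#' @param ftab optional precompiled interaction table.
#' @return `sys` with shell positions (and surrogate dipoles) updated.
#' @export
minimize_shells <- function(sys, ff, tol = 1e-4, max_iter = 500, ftab = NULL) {
  ns <- n_shells(sys)
  if (ns == 0) return(sys)
  if (is.null(ftab)) ftab <- compile_interactions(sys, ff)
  emb <- sys$embedding
  if (!is.null(emb) && emb$mode == "dynamical") emb$mode <- "scf"
  eval_at <- function(x) {
    s2 <- sys; s2$shells$pos <- matrix(x, ns, 3)
    eval_forces(s2, ftab, emb)
  }
  fn <- function(x) eval_at(x)$pot
  gr <- function(x) as.numeric(-eval_at(x)$f_shell)
  x0 <- as.numeric(sys$shells$pos)
  res_max <- function(x) {
    g <- matrix(gr(x), ns, 3)
    sqrt(max(rowSums(g^2)))
  }
  x <- x0
  # polishing rounds: optim's own stop tests are on the projected gradient
  # components, ours is the per-shell force norm
  for (round in 1:5) {
    opt <- stats::optim(x, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = max_iter, factr = 1,
                                       pgtol = tol / 30))
    x <- opt$par
    if (res_max(x) < tol) break
  }
  if (res_max(x) >= tol)
    stop("shell minimization did not converge; residual force ",
         format(res_max(x)), " eV/A")
  ev <- eval_at(x)
  sys$shells$pos <- matrix(x, ns, 3)
  if (!is.null(sys$embedding))
    sys$embedding$dipole <- ev$emb$dipole %||% sys$embedding$dipole
  sys
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Relax a full structure (cores and shells)
#'
#' Quasi-Newton (L-BFGS-B) minimization of the total energy over all core
#' and shell coordinates, until the largest per-site force norm falls below
#' `tol`. Useful for preparing gently vibrating starting structures (e.g.
#' clusters at a local minimum before low-temperature dynamics).
#'
#' @inheritParams minimize_shells
#' @param tol force tolerance (eV/A), default 1e-3.
#' @return `sys` with core and shell positions updated.
#' @export
minimize_structure <- function(sys, ff, tol = 1e-3, max_iter = 2000, ftab = NULL) {
  n <- n_atoms(sys); ns <- n_shells(sys)
  if (is.null(ftab)) ftab <- compile_interactions(sys, ff)
  emb <- sys$embedding
  if (!is.null(emb) && emb$mode == "dynamical") emb$mode <- "scf"
  unpack <- function(x) {
    s2 <- sys
    s2$pos <- matrix(x[seq_len(3 * n)], n, 3)
    if (ns > 0) s2$shells$pos <- matrix(x[3 * n + seq_len(3 * ns)], ns, 3)
    s2
  }
  eval_at <- function(x) eval_forces(unpack(x), ftab, emb)
  fn <- function(x) eval_at(x)$pot
  gr <- function(x) {
    ev <- eval_at(x)
    -c(as.numeric(ev$f_core), if (ns > 0) as.numeric(ev$f_shell))
  }
  x <- c(as.numeric(sys$pos), if (ns > 0) as.numeric(sys$shells$pos))
  res_max <- function(x) {
    g <- matrix(gr(x), ncol = 3)
    sqrt(max(rowSums(g^2)))
  }
  for (round in 1:5) {
    opt <- stats::optim(x, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = max_iter, factr = 1,
                                       pgtol = tol / 30))
    x <- opt$par
    if (res_max(x) < tol) break
  }
  if (res_max(x) >= tol)
    stop("structure minimization did not converge; residual force ",
         format(res_max(x)), " eV/A")
  out <- unpack(x)
  if (!is.null(out$embedding)) {
    ev <- eval_at(x)
    out$embedding$dipole <- ev$emb$dipole %||% out$embedding$dipole
  }
  out
}

#' One velocity-Verlet step with a generic force provider
#'
#' Advances cores and shells (extended-Lagrangian mode) by one step of
#' velocity Verlet under the forces returned by `forces_provider(sys)`,
#' which must return a list with `f_core`, `f_shell` (eV/A) and `pot` (eV).
#' Used for small fixtures and cross-checks; production runs use
#' [run_md()], which keeps the interaction tables compiled.
#'
#' @param sys a `particle_system` with velocities.
#' @param config an `integrator_config`.
#' @param forces_provider function of the system returning forces.
#' @param forces optional forces at the current positions (avoids one call).
#' @return list with the advanced `sys`, current `forces` and `pot`.
#' @export
nve_step <- function(sys, config, forces_provider, forces = NULL) {
  dt <- config$timestep
  if (is.null(forces)) forces <- forces_provider(sys)
  inv_mc <- 1 / (sys$mass * .MV2E)
  sys$vel <- sys$vel + (0.5 * dt) * forces$f_core * inv_mc
  sys$pos <- sys$pos + dt * sys$vel
  ns <- n_shells(sys)
  if (ns > 0) {
    inv_ms <- 1 / (sys$shells$mass * .MV2E)
    sys$shells$vel <- sys$shells$vel + (0.5 * dt) * forces$f_shell * inv_ms
    sys$shells$pos <- sys$shells$pos + dt * sys$shells$vel
  }
  forces <- forces_provider(sys)
  if (anyNA(forces$f_core) || anyNA(sys$pos)) stop("divergence: non-finite state")
  sys$vel <- sys$vel + (0.5 * dt) * forces$f_core * inv_mc
  if (ns > 0)
    sys$shells$vel <- sys$shells$vel + (0.5 * dt) * forces$f_shell * inv_ms
  list(sys = sys, forces = forces, pot = forces$pot)
}

#' Run molecular dynamics
#'
#' Propagates the system with velocity Verlet. NVE when `chains` is empty;
#' NVT when Nose-Hoover chains are supplied: the `nuclear` chain scales the
#' centre-of-mass velocities of the core-shell pairs against N_f k_B T_phys
#' and the `shell` chain scales the relative velocities against
#' 3 n_s k_B T_s (half-step on either side of the Verlet update,
#' Suzuki-Yoshida factorized). Systems with a dynamical-mode embedding also
#' propagate the surrogate's dipole variables, optionally coupled to a
#' `surrogate` chain.
#'
#' In `minimize_each_step` mode the shells are relaxed to their minimum at
#' every step and carry no momentum (Born-Oppenheimer-style reference
#' dynamics).
#'
#' @param sys a `particle_system` with velocities initialised.
#' @param ff a `forcefield`.
#' @param config an `integrator_config`.
#' @param nsteps number of steps.
#' @param chains `NULL`/empty list for NVE, else a named list with any of
#'   `nuclear`, `shell`, `surrogate` ([nhc_chain()] objects).
#' @param scalar_stride record the scalar series every this many steps.
#' @param frame_stride store position frames every this many steps (0 = no
#'   frames).
#' @param remove_com_dof subtract 3 from N_f in the temperature
#'   normalisation; default: yes for open systems.
#' @param minimize_first relax shells (and surrogate dipoles) before the
#'   first step (default TRUE, the cold-start prescription).
#' @return list of class `md_run`: final `sys`, `series` (data.frame of
#'   time, energies, temperatures, conserved quantity), `frames` (list of
#'   snapshots), `chains`, `config`, `nf`.
#' @export
run_md <- function(sys, ff, config = integrator_config(), nsteps,
                   chains = NULL, scalar_stride = 10, frame_stride = 0,
                   remove_com_dof = NULL, minimize_first = TRUE) {
  dt <- config$timestep
  if (is.null(remove_com_dof)) remove_com_dof <- is.null(sys$cell)
  nf <- dof_count(sys, remove_com_dof)
  ns <- n_shells(sys)
  minimize_mode <- config$shell_mode == "minimize_each_step"
  if (ns > 0 && minimize_first)
    sys <- minimize_shells(sys, ff, tol = config$shell_force_tol,
                           max_iter = config$max_minimizer_iterations)
  if (minimize_mode && ns > 0) sys$shells$vel[] <- 0
  emb <- sys$embedding
  if (!is.null(emb) && minimize_mode && emb$mode == "dynamical") emb$mode <- "scf"
  dyn_dip <- !is.null(emb) && emb$mode == "dynamical" && any(emb$polarizable)
  ftab <- compile_interactions(sys, ff)

  core_inertia <- sys$mass
  if (minimize_mode && ns > 0) {
    # massless minimized shells: the core carries the full atomic inertia
    core_inertia[sys$shells$owner] <- core_inertia[sys$shells$owner] + sys$shells$mass
  }
  inv_mc <- 1 / (core_inertia * .MV2E)
  inv_ms <- if (ns > 0) 1 / (sys$shells$mass * .MV2E) else numeric(0)
  m_dip <- if (dyn_dip) emb$dipole_mass * .MV2E else NULL

  chains <- chains %||% list()
  has_nuc <- !is.null(chains$nuclear)
  has_sh <- !is.null(chains$shell) && ns > 0 && !minimize_mode
  has_sur <- !is.null(chains$surrogate) && dyn_dip

  fr <- eval_forces(sys, ftab, emb)
  emb <- fr$emb %||% emb

  nrec <- length(seq(0, nsteps, by = scalar_stride))
  series <- matrix(NA_real_, nrec, 10)
  colnames(series) <- c("step", "time_fs", "e_pot_eV", "e_kin_nuclear_eV",
                        "e_kin_shell_eV", "e_kin_dip_eV", "e_total_eV",
                        "conserved_eV", "T_phys_K", "T_s_K")
  frames <- list()
  irec <- 0

  apply_chains <- function() {
    # half-step NHC on the COM / relative / dipole subspaces
    if (!(has_nuc || has_sh || has_sur)) return(invisible(NULL))
    if (has_nuc || has_sh) {
      d <- decompose_pairs(sys)
      if (has_nuc) {
        twoK <- .MV2E * sum(d$pair_mass * rowSums(d$com_vel^2))
        pr <- nhc_propagate(chains$nuclear, twoK, 0.5 * dt)
        chains$nuclear <<- pr$chain
        d$com_vel <- d$com_vel * pr$scale
      }
      if (has_sh) {
        twoK <- .MV2E * sum(d$red_mass * rowSums(d$rel_vel^2))
        pr <- nhc_propagate(chains$shell, twoK, 0.5 * dt)
        chains$shell <<- pr$chain
        d$rel_vel <- d$rel_vel * pr$scale
      }
      sys <<- recompose_pairs(sys, d)
    }
    if (has_sur) {
      twoK <- m_dip * sum(emb$dipole_vel^2)
      pr <- nhc_propagate(chains$surrogate, twoK, 0.5 * dt)
      chains$surrogate <<- pr$chain
      emb$dipole_vel <<- emb$dipole_vel * pr$scale
    }
    invisible(NULL)
  }

  record <- function(step) {
    irec <<- irec + 1
    d <- decompose_pairs(sys)
    ek_nuc <- 0.5 * .MV2E * sum(d$pair_mass * rowSums(d$com_vel^2))
    ek_sh <- if (ns > 0) 0.5 * .MV2E * sum(d$red_mass * rowSums(d$rel_vel^2)) else 0
    ek_dip <- if (dyn_dip) 0.5 * m_dip * sum(emb$dipole_vel^2) else 0
    tot <- fr$pot + ek_nuc + ek_sh + ek_dip
    cons <- conserved_quantity(tot, Filter(Negate(is.null), chains))
    series[irec, ] <<- c(step, step * dt, fr$pot, ek_nuc, ek_sh, ek_dip,
                         tot, cons,
                         physical_temperature(d, nf),
                         if (ns > 0) shell_temperature(d) else NA_real_)
  }

  record(0)
  if (frame_stride > 0)
    frames[[1]] <- list(step = 0, time = 0, pos = sys$pos,
                        shell_pos = if (ns > 0) sys$shells$pos else NULL)

  for (step in seq_len(nsteps)) {
    apply_chains()
    # half kick
    sys$vel <- sys$vel + (0.5 * dt) * fr$f_core * inv_mc
    if (ns > 0 && !minimize_mode)
      sys$shells$vel <- sys$shells$vel + (0.5 * dt) * fr$f_shell * inv_ms
    if (dyn_dip)
      emb$dipole_vel <- emb$dipole_vel + (0.5 * dt) * fr$f_dip / m_dip
    # drift
    sys$pos <- sys$pos + dt * sys$vel
    if (ns > 0) {
      if (minimize_mode) {
        sys <- minimize_shells(sys, ff, tol = config$shell_force_tol,
                               max_iter = config$max_minimizer_iterations,
                               ftab = ftab)
      } else {
        sys$shells$pos <- sys$shells$pos + dt * sys$shells$vel
      }
    }
    if (dyn_dip) emb$dipole <- emb$dipole + dt * emb$dipole_vel
    # forces
    fr <- eval_forces(sys, ftab, emb)
    emb <- fr$emb %||% emb
    if (!all(is.finite(fr$f_core))) stop("divergence: non-finite forces at step ", step)
    # half kick
    sys$vel <- sys$vel + (0.5 * dt) * fr$f_core * inv_mc
    if (ns > 0 && !minimize_mode)
      sys$shells$vel <- sys$shells$vel + (0.5 * dt) * fr$f_shell * inv_ms
    if (dyn_dip)
      emb$dipole_vel <- emb$dipole_vel + (0.5 * dt) * fr$f_dip / m_dip
    apply_chains()
    if (step %% scalar_stride == 0) record(step)
    if (frame_stride > 0 && step %% frame_stride == 0)
      frames[[length(frames) + 1]] <-
        list(step = step, time = step * dt, pos = sys$pos,
             shell_pos = if (ns > 0) sys$shells$pos else NULL)
  }
  if (!is.null(emb)) sys$embedding <- emb
  structure(list(sys = sys, series = as.data.frame(series[seq_len(irec), , drop = FALSE]),
                 frames = frames, chains = chains, config = config, nf = nf),
            class = "md_run")
}

#' @export
print.md_run <- function(x, ...) {
  s <- x$series
  cat("md_run:", nrow(s), "records,", max(s$time_fs), "fs\n")
  cat("  <T_phys> =", signif(mean(s$T_phys_K), 5), "K")
  if (!all(is.na(s$T_s_K))) cat("  <T_s> =", signif(mean(s$T_s_K), 4), "K")
  cat("\n  conserved quantity range:",
      format(diff(range(s$conserved_eV)), digits = 4), "eV\n")
  invisible(x)
}

#' Adiabaticity monitor
#'
#' Diagnoses how closely an extended-Lagrangian trajectory tracks the
#' adiabatic (minimized-shell) surface: shell-temperature statistics from
#' the scalar series, and the maximum per-shell displacement from the
#' instantaneously minimized shell positions, recomputed on the stored
#' frames. Trajectories in minimize-each-step mode report identically zero
#' displacement.
#'
#' @param run an `md_run` with frames.
#' @param ff the `forcefield` used for the run.
#' @param ts_threshold flag the run if max T_s exceeds this (K), default 10.
#' @param every check every `every`-th stored frame.
#' @return list with `mean_Ts`, `max_Ts`, `max_displacement` (A),
#'   `flagged`, and the per-frame displacement series.
#' @export
adiabaticity_monitor <- function(run, ff, ts_threshold = 10, every = 1) {
  sys <- run$sys
  ts <- run$series$T_s_K
  disp <- numeric(0)
  if (length(run$frames) > 0 && n_shells(sys) > 0) {
    idx <- seq(1, length(run$frames), by = every)
    minimize_mode <- run$config$shell_mode == "minimize_each_step"
    disp <- vapply(idx, function(i) {
      f <- run$frames[[i]]
      if (minimize_mode) return(0)
      s2 <- sys
      s2$pos <- f$pos
      s2$shells$pos <- f$shell_pos
      s2min <- minimize_shells(s2, ff, tol = run$config$shell_force_tol,
                               max_iter = run$config$max_minimizer_iterations)
      sqrt(max(rowSums((s2min$shells$pos - f$shell_pos)^2)))
    }, 0)
  }
  mean_ts <- if (all(is.na(ts))) NA_real_ else mean(ts, na.rm = TRUE)
  max_ts <- if (all(is.na(ts))) NA_real_ else max(ts, na.rm = TRUE)
  list(mean_Ts = mean_ts, max_Ts = max_ts,
       max_displacement = if (length(disp)) max(disp) else NA_real_,
       flagged = isTRUE(max_ts > ts_threshold),
       displacement = disp)
}
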