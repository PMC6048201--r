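test_that("temperature estimators invert their definitions and match brute force", {
  kB <- units_shellmd()$kB
  mv2 <- units_shellmd()$mv2_to_eV
  sys <- random_pair_system(n = 6, seed = 2)
  d <- decompose_pairs(sys)
  # zero velocities -> 0 K
  d0 <- d; d0$com_vel[] <- 0; d0$rel_vel[] <- 0
  expect_equal(physical_temperature(d0, 18), 0)
  expect_equal(shell_temperature(d0), 0)
  # single pair tuned so Mbar |Sdot|^2 = 3 kB 300
  sys1 <- particle_system("O", c(0, 0, 0), 15.999, 0,
                          shells = list(owner = 1, pos = c(0, 0, 0), mass = 0.2,
                                        charge = 0, k = 1))
  v <- sqrt(3 * kB * 300 / (16.199 * mv2))
  sys1$vel[1, ] <- v / sqrt(3)
  sys1$shells$vel[1, ] <- v / sqrt(3)
  expect_equal(physical_temperature(decompose_pairs(sys1), 3), 300,
               tolerance = 1e-10)
  # single shell with mbar |sdot|^2 = 3 kB * 1
  sys1$shells$vel[1, ] <- sys1$vel[1, ] -
    sqrt(3 * kB * 1 / (decompose_pairs(sys1)$red_mass[1] * mv2)) / sqrt(3)
  expect_equal(shell_temperature(decompose_pairs(sys1)), 1, tolerance = 1e-10)
  # brute-force sums
  t_brute <- mv2 * sum(d$pair_mass * rowSums(d$com_vel^2)) / (18 * kB)
  expect_equal(physical_temperature(d, 18), t_brute, tolerance = 1e-12)
  ts_brute <- mv2 * sum(d$red_mass * rowSums(d$rel_vel^2)) / (3 * 6 * kB)
  expect_equal(shell_temperature(d), ts_brute, tolerance = 1e-12)
  # no shells -> explicit error, not zero
  bare <- particle_system("Si", c(0, 0, 0), 28, 0)
  expect_error(shell_temperature(decompose_pairs(bare)), "no shells")
})

test_that("an isolated core-shell pair oscillates at sqrt(kappa/mbar)", {
  ff <- load_pmzhb()
  sys <- particle_system("O", c(0, 0, 0), 15.999, 0,
                         shells = list(owner = 1, pos = c(0.05, 0, 0), mass = 0.2,
                                       charge = 0, k = 99.4732))
  ftab <- compile_interactions(sys, ff, coulomb = FALSE)
  prov <- function(s) {
    ev <- mm_energy_forces(s, ff, ftab)
    list(f_core = ev$f_core, f_shell = ev$f_shell, pot = ev$energy$total)
  }
  cfg <- integrator_config(timestep = 0.02)
  mbar <- 15.999 * 0.2 / 16.199
  omega <- sqrt(99.4732 / (mbar * units_shellmd()$mv2_to_eV))
  crossings <- c(); s_prev <- NULL
  st <- list(sys = sys, forces = NULL)
  for (i in 1:1500) {
    st <- nve_step(st$sys, cfg, prov, st$forces)
    sx <- decompose_pairs(st$sys)$rel_pos[1, 1]
    if (!is.null(s_prev) && s_prev < 0 && sx >= 0) crossings <- c(crossings, i)
    s_prev <- sx
  }
  period <- mean(diff(crossings)) * cfg$timestep
  expect_equal(period, 2 * pi / omega, tolerance = 1e-3)
  # zero forces, zero velocities: state unchanged
  free <- particle_system("Ar", c(1, 2, 3), 40, 0)
  prov0 <- function(s) list(f_core = matrix(0, 1, 3), f_shell = matrix(0, 0, 3), pot = 0)
  st0 <- nve_step(free, integrator_config(timestep = 0.5), prov0)
  expect_equal(st0$sys$pos, free$pos)
  expect_equal(st0$sys$vel, free$vel)
  # non-finite forces raise a divergence error
  provNA <- function(s) list(f_core = matrix(NaN, 1, 3), f_shell = matrix(0, 0, 3), pot = 0)
  expect_error(nve_step(free, cfg, provNA), "divergence")
})

test_that("NVE conserves momentum and its drift scales like dt^2", {
  ff <- load_water_ff()
  sys <- build_water_cluster(3, seed = 5, ff = ff)
  sys <- initialize_velocities(sys, 200, seed = 6)
  p0 <- colSums(sys$vel * sys$mass) + colSums(sys$shells$vel * sys$shells$mass)
  drift_at <- function(dt, nsteps) {
    run <- run_md(sys, ff, integrator_config(timestep = dt), nsteps,
                  scalar_stride = 5)
    s <- run$series
    list(run = run,
         fluct = diff(range(s$e_total_eV)))
  }
  r1 <- drift_at(0.2, 1500)
  p1 <- colSums(r1$run$sys$vel * sys$mass) +
    colSums(r1$run$sys$shells$vel * sys$shells$mass)
  expect_lt(max(abs(p1 - p0)), 1e-10)
  # halving the timestep shrinks the energy fluctuation ~4x (symplectic, O(dt^2))
  r2 <- drift_at(0.1, 3000)
  ratio <- r1$fluct / r2$fluct
  expect_gt(ratio, 2.5)
  expect_lt(ratio, 6)
})

test_that("Cartesian and COM/relative propagation produce identical trajectories", {
  ff <- load_water_ff()
  sys0 <- build_water_cluster(3, seed = 9, ff = ff)
  sys0 <- initialize_velocities(sys0, 150, seed = 10)
  sys0 <- minimize_shells(sys0, ff)
  ftab <- compile_interactions(sys0, ff)
  prov <- function(s) {
    ev <- mm_energy_forces(s, ff, ftab)
    list(f_core = ev$f_core, f_shell = ev$f_shell, pot = ev$energy$total)
  }
  dt <- 0.1
  cfg <- integrator_config(timestep = dt)
  # route 1: Cartesian velocity Verlet
  cart <- sys0
  st <- list(sys = cart, forces = NULL)
  for (i in 1:100) st <- nve_step(st$sys, cfg, prov, st$forces)
  cart <- st$sys
  # route 2: velocity Verlet on the COM/relative coordinates with the
  # transformed forces (Mbar S" = F^S, mbar s" = f^s), recomposed each step
  mv2 <- units_shellmd()$mv2_to_eV
  sys <- sys0
  f <- prov(sys)
  for (i in 1:100) {
    d <- decompose_pairs(sys)
    tf <- transform_forces(f$f_core, f$f_shell, sys)
    d$com_vel <- d$com_vel + (0.5 * dt) * tf$com / (d$pair_mass * mv2)
    d$rel_vel <- d$rel_vel + (0.5 * dt) * tf$rel / (d$red_mass * mv2)
    d$com_pos <- d$com_pos + dt * d$com_vel
    d$rel_pos <- d$rel_pos + dt * d$rel_vel
    sys <- recompose_pairs(sys, d)
    f <- prov(sys)
    d <- decompose_pairs(sys)
    tf <- transform_forces(f$f_core, f$f_shell, sys)
    d$com_vel <- d$com_vel + (0.5 * dt) * tf$com / (d$pair_mass * mv2)
    d$rel_vel <- d$rel_vel + (0.5 * dt) * tf$rel / (d$red_mass * mv2)
    sys <- recompose_pairs(sys, d)
  }
  expect_lt(max(abs(sys$pos - cart$pos)), 1e-9)
  expect_lt(max(abs(sys$shells$pos - cart$shells$pos)), 1e-9)
})

test_that("shell minimization reaches the linear-response displacement in a point-charge field", {
  ff <- load_pmzhb()
  # an isolated O core-shell pair in the quasi-uniform field of a distant charge
  sys <- particle_system(c("O", "Si"), rbind(c(0, 0, 0), c(100, 0, 0)),
                         c(15.999, 28.0855), c(1.387258, 100), # Si site abused as big charge
                         shells = list(owner = 1, pos = c(0, 0, 0), mass = 0.2,
                                       charge = -1.737258, k = 99.4732))
  sys <- minimize_shells(sys, ff, tol = 1e-8)
  efield <- 14.399645 * 100 / 100^2       # V/A at the shell
  s_expect <- 1.737258 * efield / 99.4732 # |q_s| E / kappa
  s_got <- sqrt(sum((sys$shells$pos[1, ] - 0)^2))
  expect_equal(s_got, s_expect, tolerance = 2e-3)
  # with E = 1 V/A this displacement scale is q_s/kappa = 0.017465 A/(V/A)
  expect_equal(1.737258 / 99.4732, 0.017465, tolerance = 1e-4)
  # descent: minimized energy is not above the starting energy
  sys2 <- particle_system("O", c(0, 0, 0), 15.999, 0,
                          shells = list(owner = 1, pos = c(0.3, 0.1, 0), mass = 0.2,
                                        charge = 0, k = 99.4732))
  e_before <- total_mm_energy(sys2, ff)$total
  sys2m <- minimize_shells(sys2, ff, tol = 1e-8)
  e_after <- total_mm_energy(sys2m, ff)$total
  expect_lte(e_after, e_before)
  # zero external field: shell returns to the core site
  expect_lt(max(abs(sys2m$shells$pos - sys2m$pos)), 1e-8)
  expect_lt(total_mm_energy(sys2m, ff)$spring, 1e-12)
})

test_that("the adiabaticity monitor reports cold shells and zero displacement in minimize mode", {
  ff <- load_pmzhb()
  sys <- attach_shells(build_crystal("alpha_cristobalite", c(1, 1, 1)), ff)
  sys <- initialize_velocities(sys, 300, seed = 4)
  cfg <- integrator_config(timestep = 0.2)
  run <- suppressWarnings(run_md(sys, ff, cfg, 400, scalar_stride = 10,
                                 frame_stride = 100))
  mon <- suppressWarnings(adiabaticity_monitor(run, ff))
  expect_false(mon$flagged)
  expect_lt(mon$max_Ts, 10)
  expect_true(is.finite(mon$max_displacement))
  # minimize-each-step trajectories report identically zero displacement
  wff <- load_water_ff()
  wsys <- initialize_velocities(build_water_cluster(2, seed = 3, ff = wff), 100, seed = 1)
  runm <- run_md(wsys, wff, integrator_config(timestep = 0.2,
                                              shell_mode = "minimize_each_step"),
                 20, scalar_stride = 5, frame_stride = 10)
  monm <- adiabaticity_monitor(runm, wff)
  expect_identical(unique(monm$displacement), 0)
})
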