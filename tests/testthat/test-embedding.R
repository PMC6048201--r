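test_that("the modified Coulomb kernel has the right limits and asymptotics", {
  rc <- 1.0; n <- 4
  expect_equal(modified_kernel(0, rc, n), 1 / rc, tolerance = 1e-14)
  # analytic limit at r = rc: n / ((n+1) rc), evaluated without division by zero
  expect_equal(modified_kernel(rc, rc, n), n / ((n + 1) * rc), tolerance = 1e-12)
  expect_equal(modified_kernel(10 * rc, rc, n), 1 / (10 * rc), tolerance = 1e-4)
  r <- seq(0, 3, by = 0.05)
  k <- modified_kernel(r, rc, n)
  expect_true(all(is.finite(k)))
  expect_true(all(diff(k) < 0))  # monotonically decreasing
  # derivatives are consistent with finite differences (smooth through r = rc)
  kk <- modified_kernel(c(0.5, 1.0, 1.7), rc, n, deriv = TRUE)
  h <- 1e-6
  for (i in seq_along(c(0.5, 1.0, 1.7))) {
    r0 <- c(0.5, 1.0, 1.7)[i]
    expect_equal(kk$dK[i],
                 (modified_kernel(r0 + h, rc, n) - modified_kernel(r0 - h, rc, n)) / (2 * h),
                 tolerance = 1e-6)
  }
  expect_error(modified_kernel(1, rc = -1), "rc > 0")
})

test_that("a chargeless surrogate contributes only cross-dispersion and declared bonds", {
  fx <- embedded_water_fixture(mode = "static")
  sys <- fx$sys
  sys$embedding$site_charges[] <- 0
  ee <- embedding_energy_force(sys)
  expect_identical(ee$report$core_density, 0)
  expect_identical(ee$report$shell_density, 0)
  expect_identical(ee$report$bonded_cross, 0)
  expect_true(ee$report$vdw_cross != 0)
  expect_equal(ee$report$total,
               ee$report$bonded_cross + ee$report$vdw_cross +
               ee$report$core_density + ee$report$shell_density,
               tolerance = 1e-15)
})

test_that("charge-density terms reach the point-charge limit as the width vanishes", {
  # one MM charge vs one QM Gaussian site, kernel disabled
  ff <- load_water_ff()
  sys <- particle_system(c("O", "H"), rbind(c(0, 0, 0), c(2.5, 0, 0)),
                         c(16, 1), c(0, 0.41), bonds = NULL)
  sys <- make_embedding(sys, ff, qm_atoms = 1, mode = "static",
                        site_charges = -0.82, kernel_n = NULL,
                        internal_bonded = FALSE)
  sys$embedding$lj <- sys$embedding$lj[0, ]   # isolate electrostatics
  exact <- 14.399645 * (-0.82) * 0.41 / 2.5
  sys$embedding$widths <- 1e-3
  e_narrow <- embedding_energy_force(sys)$report$total
  expect_equal(e_narrow, exact, tolerance = 1e-4)
  sys$embedding$widths <- 0.6
  e_wide <- embedding_energy_force(sys)$report$total
  expect_gt(abs(e_wide - exact), 1e-6)  # smearing matters at finite width
})

test_that("embedding forces are exact gradients and obey Newton's third law", {
  for (mode in c("static", "dynamical")) {
    fx <- embedded_water_fixture(mode = mode)
    sys <- fx$sys
    if (mode == "dynamical") {
      set.seed(12)
      mu <- matrix(rnorm(3 * length(sys$embedding$qm_atoms), 0, 0.02), ncol = 3)
      mu[!sys$embedding$polarizable, ] <- 0
      sys$embedding$dipole <- mu
    }
    eval_fn <- function(s) {
      ee <- embedding_energy_force(s, s$embedding)
      list(pot = ee$energy, f_core = ee$f_core, f_shell = ee$f_shell)
    }
    err <- fd_force_error(sys, eval_fn, n_core = 5, n_shell = 3, h = 1e-6)
    expect_lt(err, 1e-6)
    ee <- embedding_energy_force(sys)
    net <- colSums(ee$f_core) + colSums(ee$f_shell)
    expect_lt(max(abs(net)), 1e-8)
    # rigid translation of the whole assembly leaves the coupling unchanged
    s2 <- sys
    s2$pos <- sweep(s2$pos, 2, c(3.2, -1.1, 0.4), "+")
    s2$shells$pos <- sweep(s2$shells$pos, 2, c(3.2, -1.1, 0.4), "+")
    expect_equal(embedding_energy_force(s2)$energy, ee$energy, tolerance = 1e-10)
  }
})

test_that("SCF polarization gives the exact linear response and stationary dipoles", {
  fx <- embedded_water_fixture(mode = "scf")
  sys <- fx$sys
  # uniform external field: mu = alpha E / C exactly
  m <- length(sys$embedding$qm_atoms)
  E <- matrix(rep(c(0.5, -0.2, 0.1), each = m), m, 3)
  emb <- surrogate_polarize(emb = sys$embedding, field = E)
  for (b in seq_len(m)) {
    if (sys$embedding$polarizable[b])
      expect_equal(emb$dipole[b, ], sys$embedding$alpha[b] * E[b, ] / 14.399645,
                   tolerance = 1e-12)
    else expect_equal(emb$dipole[b, ], c(0, 0, 0))
  }
  # zero field -> zero induced dipoles
  emb0 <- surrogate_polarize(emb = sys$embedding, field = matrix(0, m, 3))
  expect_true(all(emb0$dipole == 0))
  # self-consistent solution is stationary: -dE/dmu = 0 at the fixed point
  emb <- surrogate_polarize(sys, sys$embedding)
  ee <- embedding_energy_force(sys, emb)
  expect_lt(max(abs(ee$f_dip)), 1e-7)
  # surrogate without internal dofs refuses to polarize
  none <- sys
  none$embedding$polarizable[] <- FALSE
  expect_error(surrogate_polarize(none, none$embedding), "no internal polarization")
})

test_that("dynamically propagated dipoles track the SCF solution adiabatically", {
  fx <- embedded_water_fixture(mode = "dynamical")
  sys <- initialize_velocities(fx$sys, 300, seed = 13)
  run <- run_md(sys, fx$ff, integrator_config(timestep = 0.1), 4000,
                scalar_stride = 50)
  emb_dyn <- run$sys$embedding
  emb_scf <- surrogate_polarize(run$sys, emb_dyn)
  expect_lt(max(abs(emb_dyn$dipole - emb_scf$dipole)), 1e-3)
})

test_that("boundary bonds across the QM/MM interface are plain harmonic terms", {
  ff <- load_water_ff()
  sys <- particle_system(c("O", "O"), rbind(c(0, 0, 0), c(3.0, 0, 0)),
                         c(16, 16), c(0, -0.82))
  sys <- make_embedding(sys, ff, qm_atoms = 1, mode = "static",
                        site_charges = 0, internal_bonded = FALSE,
                        boundary_bonds = data.frame(qm = 1, mm = 2, k = 10, r0 = 2.8))
  sys$embedding$lj <- sys$embedding$lj[0, ]
  ee <- embedding_energy_force(sys)
  expect_equal(ee$report$bonded_cross, 0.5 * 10 * 0.2^2, tolerance = 1e-12)
  expect_equal(ee$f_core[1, 1], 10 * 0.2, tolerance = 1e-10)   # pulled toward the MM atom
  expect_equal(ee$f_core[2, 1], -10 * 0.2, tolerance = 1e-10)
})
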