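test_that("the bundled p-MZHB parameter set satisfies its charge and parameter constraints", {
  ff <- load_pmzhb()
  qc <- ff$charges
  q_oc <- qc$q[qc$species == "O" & qc$role == "core"]
  q_os <- qc$q[qc$species == "O" & qc$role == "shell"]
  expect_equal(q_oc + q_os, -0.35, tolerance = 1e-12)
  expect_identical(qc$q[qc$species == "Si" & qc$role == "core"], 0.70)
  # bulk SiO2 is exactly neutral: q(Si) + 2 (q_Oc + q_Os) = 0
  expect_equal(0.70 + 2 * (q_oc + q_os), 0, tolerance = 1e-12)
  expect_identical(ff$springs$kappa[ff$springs$species == "O"], 99.4732)
  expect_identical(ff$angles$theta0[ff$angles$sj == "O"], 149.8)
  expect_identical(ff$angles$theta0[ff$angles$sj == "Si"], 109.4)
  expect_identical(ff$bonds$k, 23.3)
  expect_identical(ff$bonds$r0, 1.62)
  expect_identical(shelled_species(ff), "O")
})

test_that("scalar term forms match hand arithmetic", {
  # harmonic bond: 1/2 k (r - r0)^2
  expect_equal(bond_energy(1.72, 23.3, 1.62)$energy, 0.1165, tolerance = 1e-12)
  expect_equal(bond_energy(1.62, 23.3, 1.62)$energy, 0)
  expect_equal(bond_energy(1.62, 23.3, 1.62)$dEdx, 0)
  d <- 0.07
  expect_equal(bond_energy(1.62 + d, 23.3, 1.62)$energy,
               bond_energy(1.62 - d, 23.3, 1.62)$energy)
  expect_error(bond_energy(-0.1, 23.3, 1.62), "positive")

  # harmonic angle: O-Si-O displaced by 10 degrees
  th0 <- 109.4 * pi / 180
  expect_equal(angle_energy(th0 + 10 * pi / 180, 6.061057, th0)$energy,
               0.5 * 6.061057 * (10 * pi / 180)^2, tolerance = 1e-12)
  expect_equal(0.5 * 6.061057 * (10 * pi / 180)^2, 0.092316, tolerance = 1e-5)

  # LJ: zero at sigma, -eps at the minimum
  expect_equal(lj_energy(1.77, 0.00324, 1.77)$energy, 0, tolerance = 1e-15)
  expect_equal(lj_energy(2^(1/6) * 1.77, 0.00324, 1.77)$energy, -0.00324,
               tolerance = 1e-12)
  cb <- lj_combine(0.00864, 2.200, 0.00324, 1.770)
  expect_equal(cb$eps, sqrt(0.00864 * 0.00324), tolerance = 1e-12)
  expect_equal(cb$sigma, 1.985)

  # core-shell spring
  expect_equal(spring_energy(0.1, 99.4732)$energy, 0.497366, tolerance = 1e-12)
  expect_equal(spring_energy(0, 99.4732)$energy, 0)
})

test_that("force-field files round-trip bit-exactly", {
  ff <- load_pmzhb()
  path <- tempfile(fileext = ".ff")
  write_forcefield(ff, path)
  ff2 <- read_forcefield(path)
  expect_identical(ff2$charges$q, ff$charges$q)
  expect_identical(ff2$bonds$k, ff$bonds$k)
  expect_identical(ff2$bonds$r0, ff$bonds$r0)
  expect_identical(ff2$angles$k, ff$angles$k)
  expect_identical(ff2$angles$theta0, ff$angles$theta0)
  expect_identical(ff2$lj$eps, ff$lj$eps)
  expect_identical(ff2$springs$kappa, ff$springs$kappa)
  expect_identical(ff2$exclusion_policy, ff$exclusion_policy)
  # the installed preset file matches the in-code preset
  bundled <- read_forcefield(system.file("extdata", "pmzhb.ff", package = "shellmd"))
  expect_identical(bundled$charges$q, ff$charges$q)
  expect_identical(bundled$springs$kappa, ff$springs$kappa)
})

test_that("energy report decomposes consistently and vanishes on the ideal reference", {
  ff <- load_pmzhb()
  sys <- attach_shells(build_crystal("alpha_cristobalite", c(2, 2, 2)), ff)
  rep <- total_mm_energy(sys, ff)
  expect_equal(rep$total,
               rep$bond + rep$angle + rep$lj + rep$coulomb + rep$spring,
               tolerance = 1e-12)
  # shells exactly on cores: spring is identically zero
  expect_identical(rep$spring, 0)
  # single displaced shell changes only spring + electrostatics
  sys2 <- sys
  sys2$shells$pos[1, 1] <- sys2$shells$pos[1, 1] + 0.05
  rep2 <- total_mm_energy(sys2, ff)
  expect_equal(rep2$spring, 0.5 * 99.4732 * 0.05^2, tolerance = 1e-10)
  expect_equal(rep2$total - rep$total,
               (rep2$bond - rep$bond) + (rep2$angle - rep$angle) +
               (rep2$lj - rep$lj) + (rep2$coulomb - rep$coulomb) + rep2$spring,
               tolerance = 1e-12)
})

test_that("MM energy is invariant under rigid motions and obeys Newton's third law", {
  ff <- load_pmzhb()
  sys <- open_fragment()
  e0 <- total_mm_energy(sys, ff)$total
  # rigid translation
  sys_t <- sys
  sys_t$pos <- sweep(sys_t$pos, 2, c(1.3, -2.1, 0.7), "+")
  sys_t$shells$pos <- sweep(sys_t$shells$pos, 2, c(1.3, -2.1, 0.7), "+")
  expect_equal(total_mm_energy(sys_t, ff)$total, e0, tolerance = 1e-10)
  # rigid rotation (open system)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  sys_r <- sys
  sys_r$pos <- sys$pos %*% t(R)
  sys_r$shells$pos <- sys$shells$pos %*% t(R)
  expect_equal(total_mm_energy(sys_r, ff)$total, e0, tolerance = 1e-10)
  # forces sum to zero
  out <- mm_energy_forces(sys, ff)
  expect_lt(max(abs(colSums(out$f_core) + colSums(out$f_shell))), 1e-8)
  # periodic system: translation invariance
  sysp <- perturbed_cristobalite(c(2, 2, 2))
  e0p <- total_mm_energy(sysp, ff)$total
  sysp$pos <- sweep(sysp$pos, 2, c(0.9, 1.7, -0.4), "+")
  sysp$shells$pos <- sweep(sysp$shells$pos, 2, c(0.9, 1.7, -0.4), "+")
  expect_equal(total_mm_energy(sysp, ff)$total, e0p, tolerance = 1e-9)
})

test_that("analytic forces match central finite differences", {
  ff <- load_pmzhb()
  err_open <- fd_force_error(open_fragment(), mm_eval_fn(ff), n_core = 5, n_shell = 4)
  expect_lt(err_open, 1e-6)
  sysp <- perturbed_cristobalite(c(2, 2, 2))
  ftab <- compile_interactions(sysp, ff)
  err_per <- fd_force_error(sysp, mm_eval_fn(ff, ftab), n_core = 5, n_shell = 4)
  expect_lt(err_per, 1e-6)
})

test_that("Ewald summation reproduces the rock-salt Madelung energy and the direct sum", {
  # conventional NaCl-type cell, nearest-neighbour distance 2 A
  a <- 4
  frac <- rbind(c(0, 0, 0), c(.5, .5, 0), c(.5, 0, .5), c(0, .5, .5),
                c(.5, 0, 0), c(0, .5, 0), c(0, 0, .5), c(.5, .5, .5))
  q <- c(1, 1, 1, 1, -1, -1, -1, -1)
  pos <- frac %*% diag(a, 3)
  ew <- ewald_energy_force(pos, q, diag(a, 3), accuracy = 1e-8)
  madelung <- -(ew$energy / 4) * 2 / 14.399645
  expect_equal(madelung, 1.747565, tolerance = 1e-3)
  expect_lt(max(abs(ew$forces)), 1e-10)  # every site is an inversion centre
  # against an independent expanding-image direct sum (cubic shells of a
  # neutral cell converge for this symmetric arrangement)
  e_direct <- oracle_lattice_sum(pos, q, diag(a, 3), nimg = 12)
  expect_equal(ew$energy, e_direct, tolerance = 2e-3)
})

test_that("Ewald matches open-boundary Coulomb in the large-box limit and is extensive", {
  # zero-dipole arrangement so the conducting-boundary term vanishes fast
  pos <- rbind(c(1.1, 0.2, -0.3), c(-1.1, -0.2, 0.3),
               c(0.4, 1.3, 0.8), c(-0.4, -1.3, -0.8))
  q <- c(0.7, 0.7, -0.7, -0.7)
  e_open <- coulomb_direct(pos, q)$energy
  expect_equal(oracle_coulomb(pos, q), e_open, tolerance = 1e-10)
  e_big <- ewald_energy_force(sweep(pos, 2, 40, "+"), q, diag(80, 3),
                              accuracy = 1e-7)$energy
  expect_equal(e_big, e_open, tolerance = 1e-5)
  # exact extensivity under 2x2x2 replication
  set.seed(11)
  base <- matrix(runif(12, 0.5, 3.5), 4, 3)
  qb <- c(1, -1, 0.6, -0.6)
  cell1 <- diag(4.5, 3)
  reps <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  pos8 <- do.call(rbind, lapply(seq_len(8), function(i)
    sweep(base, 2, reps[i, ] * 4.5, "+")))
  q8 <- rep(qb, 8)
  e1 <- ewald_energy_force(base, qb, cell1, accuracy = 1e-8)$energy
  e8 <- ewald_energy_force(pos8, q8, diag(9, 3), accuracy = 1e-8)$energy
  expect_equal(e8, 8 * e1, tolerance = 1e-7)
})

test_that("non-neutral periodic systems warn and parameterization gaps error", {
  expect_warning(ewald_energy_force(rbind(c(0, 0, 0)), 1, diag(5, 3)),
                 "neutraliz")
  ff <- load_pmzhb()
  sys <- particle_system(c("Si", "N"), rbind(c(0, 0, 0), c(1.6, 0, 0)),
                         c(28, 14), c(0, 0), bonds = rbind(c(1, 2)))
  expect_error(total_mm_energy(sys, ff), "no bond parameters")
  expect_error(coulomb_direct(rbind(c(0, 0, 0), c(0, 0, 0)), c(1, -1)),
               "coincident")
})
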