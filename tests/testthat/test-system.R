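test_that("pair decomposition reproduces the worked examples", {
  # equal masses: centre of mass at the midpoint, s = R - r
  sys <- particle_system("O", c(0, 0, 0), 1.0, 0,
                         shells = list(owner = 1, pos = c(1, 0, 0), mass = 1.0,
                                       charge = 0, k = 1))
  d <- decompose_pairs(sys)
  expect_equal(d$com_pos[1, ], c(0.5, 0, 0))
  expect_equal(d$rel_pos[1, ], c(-1, 0, 0))

  # O core with a light shell: S_x = m r / (M + m)
  sys <- particle_system("O", c(0, 0, 0), 15.999, 0,
                         shells = list(owner = 1, pos = c(0.1, 0, 0), mass = 0.2,
                                       charge = 0, k = 99.4732))
  d <- decompose_pairs(sys)
  expect_equal(d$com_pos[1, 1], 0.2 * 0.1 / 16.199, tolerance = 1e-10)
  expect_equal(d$pair_mass[1], 16.199)
  expect_equal(d$red_mass[1], 15.999 * 0.2 / 16.199)
  # recompose inverts the worked example
  s2 <- recompose_pairs(sys, d)
  expect_equal(s2$pos, sys$pos, tolerance = 1e-14)
  expect_equal(s2$shells$pos, sys$shells$pos, tolerance = 1e-14)

  # near-massless shell: S -> R, reduced mass -> 0
  sys$shells$mass <- 1e-9
  d <- decompose_pairs(sys)
  expect_equal(d$com_pos[1, 1], 0, tolerance = 1e-9)
  expect_lt(d$red_mass[1], 1.1e-9)
})

test_that("decompose/recompose is the identity and kinetic energy is partition-invariant", {
  for (seed in 1:25) {
    sys <- random_pair_system(n = 5, seed = seed)
    d <- decompose_pairs(sys)
    s2 <- recompose_pairs(sys, d)
    expect_equal(s2$pos, sys$pos, tolerance = 1e-12)
    expect_equal(s2$shells$pos, sys$shells$pos, tolerance = 1e-12)
    expect_equal(s2$vel, sys$vel, tolerance = 1e-12)
    ke <- kinetic_energies(sys)
    expect_equal(ke$core + ke$shell, ke$com + ke$rel, tolerance = 1e-10)
  }
})

test_that("force transform preserves the total force and the equations of motion", {
  sys <- random_pair_system(n = 6, seed = 3)
  set.seed(4)
  f_core <- matrix(rnorm(18), 6, 3)
  f_shell <- matrix(rnorm(18), 6, 3)
  tf <- transform_forces(f_core, f_shell, sys)
  expect_equal(colSums(tf$com), colSums(f_core) + colSums(f_shell),
               tolerance = 1e-12)
  # zero forces map to zero; opposite internal forces cancel in the COM
  tf0 <- transform_forces(matrix(0, 6, 3), matrix(0, 6, 3), sys)
  expect_true(all(tf0$com == 0) && all(tf0$rel == 0))
  sys_eq <- particle_system("O", c(0, 0, 0), 1, 0,
                            shells = list(owner = 1, pos = c(1, 0, 0), mass = 1,
                                          charge = 0, k = 1))
  tfe <- transform_forces(rbind(c(1, 0, 0)), rbind(c(-1, 0, 0)), sys_eq)
  expect_equal(tfe$com[1, ], c(0, 0, 0))
  # accelerations agree: Mbar S" = F^(S), mbar s" = f^(s) vs Cartesian
  d <- decompose_pairs(sys)
  o <- sys$shells$owner
  a_core <- f_core / sys$mass
  a_shell <- f_shell / sys$shells$mass
  w <- sys$mass[o] / d$pair_mass[o]
  acc_com <- a_core[o, ] * w + a_shell * (1 - w)
  expect_equal(tf$com[o, ] / d$pair_mass[o], acc_com, tolerance = 1e-12)
  expect_equal(tf$rel / d$red_mass, a_core[o, ] - a_shell, tolerance = 1e-12)
  expect_error(transform_forces(matrix(0, 2, 3), matrix(0, 6, 3), sys), "mismatch")
})

test_that("minimum image handles cubic and triclinic cells", {
  expect_equal(minimum_image(c(9.9, 0, 0), diag(10, 3)), c(-0.1, 0, 0))
  expect_equal(minimum_image(c(4.9, 0, 0), diag(10, 3)), c(4.9, 0, 0))
  expect_equal(minimum_image(c(1, 2, 3), NULL), c(1, 2, 3))
  # triclinic vs brute-force search over 27 images
  cell <- rbind(c(6, 0, 0), c(2.5, 5.5, 0), c(-1, 1.5, 7))
  set.seed(5)
  for (i in 1:30) {
    d <- runif(3, -10, 10)
    got <- minimum_image(d, cell)
    frac <- d %*% solve(cell)
    frac <- frac - round(frac)
    best <- Inf
    for (n1 in -1:1) for (n2 in -1:1) for (n3 in -1:1) {
      v <- (frac + c(n1, n2, n3)) %*% cell
      best <- min(best, sum(v^2))
    }
    expect_equal(sum(got^2), best, tolerance = 1e-10)
  }
  expect_error(particle_system("H", c(0, 0, 0), 1, 0, cell = matrix(0, 3, 3)),
               "singular")
})

test_that("extended-XYZ files round-trip cores, shells, cell and velocities", {
  ff <- load_pmzhb()
  sys <- attach_shells(build_crystal("alpha_cristobalite", c(1, 1, 1)), ff)
  set.seed(8)
  sys$vel <- matrix(rnorm(3 * n_atoms(sys), 0, 0.01), ncol = 3)
  sys$shells$pos <- sys$shells$pos + 0.01
  path <- tempfile(fileext = ".xyz")
  write_xyz(sys, path)
  s2 <- read_xyz(path)
  expect_equal(s2$species, sys$species)
  expect_equal(s2$pos, sys$pos, tolerance = 1e-12)
  expect_equal(s2$vel, sys$vel, tolerance = 1e-12)
  expect_equal(s2$cell, sys$cell, tolerance = 1e-12)
  expect_equal(s2$shells$owner, sys$shells$owner)
  expect_equal(s2$shells$pos, sys$shells$pos, tolerance = 1e-12)
  expect_equal(s2$shells$charge, sys$shells$charge, tolerance = 1e-12)
  expect_equal(s2$shells$k, sys$shells$k, tolerance = 1e-12)
  expect_equal(total_charge(s2), total_charge(sys), tolerance = 1e-12)
})

test_that("topology validation rejects malformed shell assignments", {
  expect_error(particle_system("O", c(0, 0, 0), 16, 0,
                               shells = list(owner = 2, pos = c(0, 0, 0),
                                             mass = 0.2, charge = 0, k = 10)),
               "owner")
  expect_error(particle_system(c("O", "O"), rbind(c(0, 0, 0), c(2, 0, 0)),
                               c(16, 16), c(0, 0),
                               shells = list(owner = c(1, 1),
                                             pos = matrix(0, 2, 3),
                                             mass = c(0.2, 0.2), charge = c(0, 0),
                                             k = c(1, 1))),
               "more than one")
  expect_error(particle_system("O", c(0, 0, 0), 16, 0,
                               shells = list(owner = 1, pos = c(0, 0, 0),
                                             mass = -0.1, charge = 0, k = 10)),
               "positive")
})
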