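two_frame_fixture <- function(b1, b2) {
  # two-atom system observed in two frames with bond lengths b1, b2
  sys <- particle_system(c("Si", "O"), rbind(c(0, 0, 0), c(b1, 0, 0)),
                         c(28, 16), c(0, 0), bonds = rbind(c(1, 2)))
  frames <- list(list(pos = rbind(c(0, 0, 0), c(b1, 0, 0))),
                 list(pos = rbind(c(0, 0, 0), c(b2, 0, 0))))
  run <- structure(list(sys = sys, frames = frames), class = "md_run")
  run
}

test_that("structural averages match hand arithmetic and are order-invariant", {
  run <- two_frame_fixture(1.60, 1.64)
  bl <- mean_bond_length(run, c("Si", "O"), discard = 0)
  expect_equal(bl$mean, 1.62, tolerance = 1e-12)
  expect_equal(bl$sd, 0.02, tolerance = 1e-12)
  # reordering the frames changes nothing
  run_r <- run; run_r$frames <- rev(run_r$frames)
  expect_equal(mean_bond_length(run_r, c("Si", "O"), discard = 0)$mean, bl$mean)
  expect_equal(mean_bond_length(run_r, c("Si", "O"), discard = 0)$sd, bl$sd)

  # angles: 108 and 112 degrees -> 110 +- 2
  sysA <- particle_system(c("O", "Si", "O"),
                          rbind(c(1, 0, 0), c(0, 0, 0), c(cos(108 * pi / 180), sin(108 * pi / 180), 0)),
                          c(16, 28, 16), c(0, 0, 0),
                          bonds = rbind(c(1, 2), c(2, 3)),
                          angles = rbind(c(1, 2, 3)))
  mk <- function(th) list(pos = rbind(c(1, 0, 0), c(0, 0, 0),
                                      c(cos(th * pi / 180), sin(th * pi / 180), 0)))
  runA <- structure(list(sys = sysA, frames = list(mk(108), mk(112))),
                    class = "md_run")
  an <- mean_angle(runA, c("O", "Si", "O"), discard = 0)
  expect_equal(an$mean, 110, tolerance = 1e-10)
  expect_equal(an$sd, 2, tolerance = 1e-10)

  # ideal lattice frame: all angles at their crystallographic values, sd ~ 0
  sys <- build_crystal("alpha_cristobalite", c(2, 2, 2))
  run1 <- structure(list(sys = sys, frames = list(list(pos = sys$pos))),
                    class = "md_run")
  b <- mean_bond_length(run1, c("Si", "O"), discard = 0)
  expect_lt(b$sd, 0.02)
  expect_equal(b$mean, 1.61, tolerance = 0.02)
  expect_error(mean_bond_length(run1, c("Si", "Si"), discard = 0), "match")
})

test_that("defect distance distributions follow the recorded Si pair", {
  ff <- load_pmzhb()
  sys <- attach_shells(build_crystal("alpha_cristobalite", c(2, 2, 2)), ff)
  vac <- create_oxygen_vacancy(sys, which(sys$species == "O")[3])
  p <- vac$defect_si_pair
  f1 <- vac$pos
  f2 <- vac$pos
  shift <- 0.05 * (f2[p[1], ] - f2[p[2], ]) / sqrt(sum((f2[p[1], ] - f2[p[2], ])^2))
  f2[p[1], ] <- f2[p[1], ] + shift
  run <- structure(list(sys = vac, frames = list(list(pos = f1), list(pos = f2))),
                   class = "md_run")
  dd <- defect_distance_distribution(run, discard = 0)
  expect_length(dd$values, 2)
  expect_equal(dd$mean, mean(dd$values), tolerance = 1e-12)
  # static frame gives a delta histogram at the single distance
  run1 <- structure(list(sys = vac, frames = list(list(pos = f1))), class = "md_run")
  dd1 <- defect_distance_distribution(run1, discard = 0)
  expect_equal(dd1$sd, 0)
  # brute-force per-frame loop oracle
  oracle <- vapply(run$frames, function(f) {
    d <- minimum_image(f$pos[p[1], ] - f$pos[p[2], ], vac$cell)
    sqrt(sum(d * d))
  }, 0)
  expect_equal(dd$values, oracle, tolerance = 1e-12)
  no_pair <- vac; no_pair$defect_si_pair <- NULL
  run$sys <- no_pair
  expect_error(defect_distance_distribution(run, discard = 0), "defect")
})

test_that("drift estimation recovers constructed slopes in both unit systems", {
  n_at <- 20
  t_fs <- seq(0, 5000, by = 10)
  # constructed series: 1e-7 a.u. per atom per ps
  e <- 27.211386 * 1e-7 * n_at * (t_fs / 1000)
  dr <- energy_drift(t_fs, e, n_at)
  expect_equal(dr$au_per_atom_ps, 1e-7, tolerance = 1e-10)
  expect_equal(dr$ev_per_atom_ps, 27.211386e-7, tolerance = 1e-10)
  # constant series: zero drift
  expect_equal(energy_drift(t_fs, rep(2.5, length(t_fs)), n_at)$au_per_atom_ps, 0)
  # white noise: drift consistent with zero at the fit-error scale
  set.seed(21)
  noise <- rnorm(length(t_fs), 0, 1e-4)
  drn <- energy_drift(t_fs, noise, n_at)
  expect_lt(abs(drn$au_per_atom_ps), 5e-8)
  expect_error(energy_drift(rep(1, 10), rnorm(10), 5), "degenerate")
})

test_that("the vacancy formation energy formula is exact and linear in x", {
  expect_equal(vacancy_formation_energy(-10, e_defect = 11.15, e_bulk = 0, x = 1),
               8.73, tolerance = 1e-12)
  expect_equal(vacancy_formation_energy(-10, e_defect = 5, e_bulk = 5, x = 0), 0)
  # default dissociation energy is the experimental 5.16 eV
  expect_equal(vacancy_formation_energy(0, 0, 0, x = 2),
               2 * vacancy_formation_energy(0, 0, 0, x = 1))
  expect_equal(vacancy_formation_energy(0, 0, 0, x = 1), 2.58)
})

test_that("temperature statistics summarise series and flag the canonical variance scale", {
  s <- data.frame(T_phys_K = rep(300, 50), T_s_K = rep(1, 50))
  st <- temperature_statistics(s, discard = 0)
  expect_equal(st$T_phys$mean, 300)
  expect_equal(st$T_phys$sd, 0)
  expect_equal(st$T_s$mean, 1)
  run <- structure(list(series = data.frame(T_phys_K = rnorm(200, 300, 10),
                                            T_s_K = rnorm(200, 1, 0.1)),
                        nf = 96), class = "md_run")
  st2 <- temperature_statistics(run, discard = 0.2)
  expect_equal(st2$canonical_rel_var, 2 / 96)
  expect_gt(st2$T_phys$sd, 0)
})
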