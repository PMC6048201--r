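# Shared fixtures and independent oracle implementations used across tests.

# random open core-shell system (every atom shelled)
random_pair_system <- function(n = 4, seed = 1) {
  set.seed(seed)
  particle_system(
    species = rep("O", n),
    pos = matrix(runif(3 * n, 0, 8), n, 3),
    mass = runif(n, 10, 30),
    charge = rep(0, n),
    vel = matrix(rnorm(3 * n, 0, 0.02), n, 3),
    shells = list(owner = seq_len(n),
                  pos = matrix(runif(3 * n, 0, 8), n, 3),
                  vel = matrix(rnorm(3 * n, 0, 0.05), n, 3),
                  mass = runif(n, 0.1, 0.5),
                  charge = rep(0, n),
                  k = runif(n, 20, 120)))
}

# brute-force Coulomb sum (independent of the compiled kernel)
oracle_coulomb <- function(pos, q) {
  e <- 0
  n <- nrow(pos)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- sqrt(sum((pos[i, ] - pos[j, ])^2))
    e <- e + 14.399645 * q[i] * q[j] / r
  }
  e
}

# direct lattice sum over expanding cubic image shells (Ewald oracle)
oracle_lattice_sum <- function(pos, q, cell, nimg = 14) {
  e <- 0
  n <- nrow(pos)
  for (n1 in -nimg:nimg) for (n2 in -nimg:nimg) for (n3 in -nimg:nimg) {
    shift <- c(n1, n2, n3) %*% cell
    zero <- n1 == 0 && n2 == 0 && n3 == 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (zero && i >= j) next
      d <- pos[i, ] - pos[j, ] + shift
      w <- if (zero) 1 else 0.5
      e <- e + w * 14.399645 * q[i] * q[j] / sqrt(sum(d * d))
    }
  }
  e
}

# water cluster with molecule 1 embedded as the QM surrogate
embedded_water_fixture <- function(n = 5, seed = 7, mode = "dynamical") {
  ff <- load_water_ff()
  sys <- build_water_cluster(n, seed = seed, ff = ff)
  qm <- which(sys$molecule == 1)
  keep <- !(sys$shells$owner %in% qm)
  sh <- sys$shells
  sys$charge[sh$owner[!keep]] <- sys$charge[sh$owner[!keep]] + sh$charge[!keep]
  sys$shells <- lapply(
    list(owner = sh$owner, pos = sh$pos, vel = sh$vel, mass = sh$mass,
         charge = sh$charge, k = sh$k),
    function(x) if (is.matrix(x)) x[keep, , drop = FALSE] else x[keep])
  sys <- make_embedding(sys, ff, qm_atoms = qm, mode = mode)
  list(sys = sys, ff = ff)
}

# finite-difference force check against the analytic forces of a
# user-supplied evaluator: eval_fn(sys) -> list(pot, f_core, f_shell)
fd_force_error <- function(sys, eval_fn, n_core = 4, n_shell = 3, h = 1e-5,
                           seed = 99) {
  set.seed(seed)
  ref <- eval_fn(sys)
  err <- 0
  for (i in sample(n_atoms(sys), min(n_core, n_atoms(sys)))) for (d in 1:3) {
    sp <- sys; sp$pos[i, d] <- sp$pos[i, d] + h
    sm <- sys; sm$pos[i, d] <- sm$pos[i, d] - h
    fn <- -(eval_fn(sp)$pot - eval_fn(sm)$pot) / (2 * h)
    err <- max(err, abs(fn - ref$f_core[i, d]))
  }
  if (n_shells(sys) > 0) {
    for (k in sample(n_shells(sys), min(n_shell, n_shells(sys)))) for (d in 1:3) {
      sp <- sys; sp$shells$pos[k, d] <- sp$shells$pos[k, d] + h
      sm <- sys; sm$shells$pos[k, d] <- sm$shells$pos[k, d] - h
      fn <- -(eval_fn(sp)$pot - eval_fn(sm)$pot) / (2 * h)
      err <- max(err, abs(fn - ref$f_shell[k, d]))
    }
  }
  err
}

mm_eval_fn <- function(ff, ftab = NULL) {
  function(sys) {
    out <- mm_energy_forces(sys, ff, ftab)
    list(pot = out$energy$total, f_core = out$f_core, f_shell = out$f_shell)
  }
}

# perturbed periodic cristobalite fragment with shells
perturbed_cristobalite <- function(rep3 = c(2, 2, 2), seed = 1, amp = 0.05) {
  ff <- load_pmzhb()
  sys <- attach_shells(build_crystal("alpha_cristobalite", rep3), ff)
  set.seed(seed)
  sys$pos <- sys$pos + matrix(rnorm(3 * n_atoms(sys), 0, amp), ncol = 3)
  sys$shells$pos <- sys$shells$pos + matrix(rnorm(3 * n_shells(sys), 0, amp / 2), ncol = 3)
  sys
}

# open (non-periodic) perturbed cristobalite fragment: cores taken from the
# crystal, cell removed, topology rebuilt from open distances
open_fragment <- function(seed = 2) {
  ff <- load_pmzhb()
  sys <- build_crystal("alpha_cristobalite", c(1, 1, 2))
  sys$cell <- NULL
  sys <- detect_topology(sys, cutoff = 2.0)
  sys <- attach_shells(sys, ff)
  set.seed(seed)
  sys$pos <- sys$pos + matrix(rnorm(3 * n_atoms(sys), 0, 0.03), ncol = 3)
  sys$shells$pos <- sys$shells$pos + matrix(rnorm(3 * n_shells(sys), 0, 0.01), ncol = 3)
  sys
}
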