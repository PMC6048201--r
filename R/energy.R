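# Interaction compilation and energy/force evaluation (wraps the C++ kernel).

cell_heights <- function(cell) {
  v <- abs(det(cell))
  cr <- function(a, b) c(a[2]*b[3]-a[3]*b[2], a[3]*b[1]-a[1]*b[3], a[1]*b[2]-a[2]*b[1])
  areas <- c(sqrt(sum(cr(cell[2, ], cell[3, ])^2)),
             sqrt(sum(cr(cell[3, ], cell[1, ])^2)),
             sqrt(sum(cr(cell[1, ], cell[2, ])^2)))
  v / areas
}

#' Ewald parameter setup
#'
#' Auto-tunes the splitting parameter alpha, the real-space cutoff and the
#' reciprocal-space vector list from a dimensionless accuracy target
#' (standard exponential error estimates: with p = -log(accuracy),
#' alpha = sqrt(p)/r_cut and k_cut = 2 alpha sqrt(p)). The real-space cutoff
#' defaults to just inside the minimum-image radius of the cell.
#'
#' @param cell 3 x 3 lattice-vector rows (A).
#' @param accuracy dimensionless accuracy target (default 1e-5).
#' @param rcut optional real-space cutoff (A).
#' @return list with `alpha`, `rcut`, `kint`, `kvec`, `coef`, `mmax`, `vol`.
#' @keywords internal
ewald_setup <- function(cell, accuracy = 1e-5, rcut = NULL) {
  h <- cell_heights(cell)
  if (is.null(rcut)) rcut <- 0.49 * min(h)
  p <- -log(accuracy)
  alpha <- sqrt(p) / rcut
  kcut <- 2 * alpha * sqrt(p)
  B <- 2 * pi * t(solve(cell))        # rows are reciprocal vectors
  anorm <- sqrt(rowSums(cell^2))
  mmax <- pmax(1L, as.integer(ceiling(kcut * anorm / (2 * pi))) + 1L)
  g <- expand.grid(m1 = 0:mmax[1], m2 = -mmax[2]:mmax[2], m3 = -mmax[3]:mmax[3])
  # half space: m1 > 0, or m1 = 0 & m2 > 0, or m1 = m2 = 0 & m3 > 0
  keep <- g$m1 > 0 | (g$m1 == 0 & g$m2 > 0) | (g$m1 == 0 & g$m2 == 0 & g$m3 > 0)
  g <- g[keep, , drop = FALSE]
  kv <- as.matrix(g) %*% B
  k2 <- rowSums(kv^2)
  keep <- k2 <= kcut^2
  g <- g[keep, , drop = FALSE]; kv <- kv[keep, , drop = FALSE]; k2 <- k2[keep]
  vol <- abs(det(cell))
  coef <- 2 * (2 * pi * .C_COUL / vol) * exp(-k2 / (4 * alpha^2)) / k2
  list(alpha = alpha, rcut = rcut,
       kint = matrix(as.integer(as.matrix(g)), ncol = 3),
       kvec = kv, coef = coef, mmax = mmax, vol = vol)
}

excl_keys_from_pairs <- function(pairs, n) {
  if (is.null(pairs) || nrow(pairs) == 0) return(numeric(0))
  i <- pmin(pairs[, 1], pairs[, 2]) - 1
  j <- pmax(pairs[, 1], pairs[, 2]) - 1
  sort(unique(i * n + j))
}

#' Compile the interaction tables of a system under a force field
#'
#' Resolves per-bond/per-angle parameters, LJ site assignments, topological
#' exclusions and (for periodic cells) the Ewald parameters into a static
#' table consumed by the compiled kernel. Atoms in the system's QM region
#' are removed from all MM terms (their charges are zeroed and their bonded
#' terms dropped); their interactions are supplied by the embedding layer.
#'
#' @param sys a `particle_system`.
#' @param ff a `forcefield`.
#' @param coulomb logical, include electrostatics.
#' @return An opaque list used by [mm_energy_forces()].
#' @export
compile_interactions <- function(sys, ff, coulomb = TRUE) {
  n <- n_atoms(sys); ns <- n_shells(sys)
  qm <- logical(n); qm[sys$qm_atoms] <- TRUE
  if (ns > 0 && any(qm[sys$shells$owner]))
    stop("QM atoms cannot carry MM shells")
  # geometry site per atom (0-based site index: cores 0..n-1, shells n..)
  geom <- 0:(n - 1)
  if (ns > 0) geom[sys$shells$owner] <- n + seq_len(ns) - 1L

  bm <- sys$bonds
  if (nrow(bm)) bm <- bm[!(qm[bm[, 1]] | qm[bm[, 2]]), , drop = FALSE]
  bk <- br0 <- numeric(nrow(bm))
  if (nrow(bm)) {
    for (b in seq_len(nrow(bm))) {
      p <- ff_bond_params(ff, sys$species[bm[b, 1]], sys$species[bm[b, 2]])
      bk[b] <- p$k; br0[b] <- p$r0
    }
  }
  am <- sys$angles
  if (nrow(am)) am <- am[!(qm[am[, 1]] | qm[am[, 2]] | qm[am[, 3]]), , drop = FALSE]
  akth <- ath0 <- numeric(nrow(am))
  if (nrow(am)) {
    for (a in seq_len(nrow(am))) {
      p <- ff_angle_params(ff, sys$species[am[a, 1]], sys$species[am[a, 2]],
                           sys$species[am[a, 3]])
      akth[a] <- p$k; ath0[a] <- p$theta0 * pi / 180
    }
  }

  eps <- sig <- numeric(n)
  for (srow in seq_len(nrow(ff$lj))) {
    hit <- sys$species == ff$lj$species[srow] & !qm
    eps[hit] <- ff$lj$eps[srow]; sig[hit] <- ff$lj$sigma[srow]
  }

  q <- sys$charge
  q[qm] <- 0
  q <- c(q, if (ns > 0) sys$shells$charge else numeric(0))

  pairs12 <- bm
  pairs13 <- if (nrow(am)) am[, c(1, 3), drop = FALSE] else matrix(integer(0), 0, 2)
  excl <- switch(ff$exclusion_policy,
                 "none" = matrix(integer(0), 0, 2),
                 "12" = pairs12,
                 "12-13" = rbind(pairs12, pairs13))

  pbc <- !is.null(sys$cell)
  lj_cut <- ff$lj_cutoff
  ew <- NULL
  if (pbc) {
    lj_cut <- min(lj_cut, 0.49 * min(cell_heights(sys$cell)))
    if (coulomb && any(q != 0)) {
      ew <- ewald_setup(sys$cell, ff$ewald_accuracy)
      if (abs(sum(q)) > 1e-8)
        warning("non-neutral periodic system: applying neutralizing background")
      if (nrow(excl) > 0 && ew$rcut < 4.5)
        warning("real-space Ewald cutoff (", signif(ew$rcut, 3),
                " A) is comparable to excluded-pair distances; ",
                "use a larger supercell for reliable energies")
    }
  }

  list(n = n, ns = ns,
       owner = if (ns > 0) sys$shells$owner - 1L else integer(0),
       geom = as.integer(geom),
       q = q,
       cell = sys$cell,
       bond_i = as.integer(bm[, 1] - 1L), bond_j = as.integer(bm[, 2] - 1L),
       bond_k = bk, bond_r0 = br0,
       ang_i = as.integer(am[, 1] - 1L), ang_j = as.integer(am[, 2] - 1L),
       ang_k = as.integer(am[, 3] - 1L), ang_kth = akth, ang_th0 = ath0,
       lj_eps = eps, lj_sig = sig,
       lj_atoms = as.integer(which(eps > 0) - 1L),
       lj_cut = lj_cut, lj_shift = as.integer(ff$lj_shift),
       kappa = if (ns > 0) sys$shells$k else numeric(0),
       excl_key = excl_keys_from_pairs(excl, n),
       coul_on = as.integer(coulomb),
       ew_alpha = if (is.null(ew)) 0 else ew$alpha,
       ew_rcut = if (is.null(ew)) 0 else ew$rcut,
       ew_kint = if (is.null(ew)) matrix(integer(0), 0, 3) else ew$kint,
       ew_kvec = if (is.null(ew)) matrix(0, 0, 3) else ew$kvec,
       ew_coef = if (is.null(ew)) numeric(0) else ew$coef,
       ew_mmax = if (is.null(ew)) integer(3) else ew$mmax,
       ew_vol = if (is.null(ew)) 1 else ew$vol)
}

#' MM energy and forces
#'
#' Evaluates the shell-model MM energy E_b + E_nb + springs and its analytic
#' forces on every core and shell. Open systems use direct pairwise Coulomb;
#' periodic systems use Ewald summation.
#'
#' @param sys a `particle_system`.
#' @param ff a `forcefield`.
#' @param ftab optional precompiled table from [compile_interactions()]
#'   (topology and parameters are static along a trajectory, so compiling
#'   once per run avoids per-step overhead).
#' @return list with `energy` (an energy report: `bond`, `angle`, `lj`,
#'   `coulomb`, `spring`, `total`, all eV), `f_core` (n x 3, eV/A) and
#'   `f_shell` (ns x 3).
#' @export
mm_energy_forces <- function(sys, ff, ftab = NULL) {
  if (is.null(ftab)) ftab <- compile_interactions(sys, ff)
  sh_pos <- if (n_shells(sys) > 0) sys$shells$pos else matrix(0, 0, 3)
  out <- cpp_energy_forces(ftab, sys$pos, sh_pos)
  rep <- list(bond = out$bond, angle = out$angle, lj = out$lj,
              coulomb = out$coulomb, spring = out$spring)
  rep$total <- out$bond + out$angle + out$lj + out$coulomb + out$spring
  list(energy = rep, f_core = out$f_core, f_shell = out$f_shell)
}

#' Total MM energy report
#'
#' @inheritParams mm_energy_forces
#' @return The energy report component of [mm_energy_forces()].
#' @export
total_mm_energy <- function(sys, ff, ftab = NULL) {
  mm_energy_forces(sys, ff, ftab)$energy
}

charges_only_ftab <- function(pos, charge, cell = NULL, exclusions = NULL,
                              accuracy = 1e-6, rcut = NULL) {
  n <- nrow(pos)
  ew <- NULL
  if (!is.null(cell)) ew <- ewald_setup(cell, accuracy, rcut)
  list(n = n, ns = 0L, owner = integer(0), geom = 0:(n - 1),
       q = as.numeric(charge), cell = cell,
       bond_i = integer(0), bond_j = integer(0), bond_k = numeric(0),
       bond_r0 = numeric(0),
       ang_i = integer(0), ang_j = integer(0), ang_k = integer(0),
       ang_kth = numeric(0), ang_th0 = numeric(0),
       lj_eps = numeric(n), lj_sig = numeric(n), lj_atoms = integer(0),
       lj_cut = 1, lj_shift = 0L, kappa = numeric(0),
       excl_key = excl_keys_from_pairs(exclusions, n),
       coul_on = 1L,
       ew_alpha = if (is.null(ew)) 0 else ew$alpha,
       ew_rcut = if (is.null(ew)) 0 else ew$rcut,
       ew_kint = if (is.null(ew)) matrix(integer(0), 0, 3) else ew$kint,
       ew_kvec = if (is.null(ew)) matrix(0, 0, 3) else ew$kvec,
       ew_coef = if (is.null(ew)) numeric(0) else ew$coef,
       ew_mmax = if (is.null(ew)) integer(3) else ew$mmax,
       ew_vol = if (is.null(ew)) 1 else ew$vol)
}

#' Direct-space Coulomb energy and forces of a set of point charges
#'
#' Pairwise `C q_a q_b / r` over all sites of an open (non-periodic)
#' arrangement, minus excluded pairs.
#'
#' @param pos n x 3 positions (A).
#' @param charge charges (e).
#' @param exclusions optional 2-column matrix of 1-based excluded pairs.
#' @return list with `energy` (eV) and `forces` (n x 3, eV/A).
#' @examples
#' coulomb_direct(rbind(c(0, 0, 0), c(1, 0, 0)), c(1, -1))$energy  # -14.399645
#' @export
coulomb_direct <- function(pos, charge, exclusions = NULL) {
  pos <- as_coord_matrix(pos, "pos")
  ftab <- charges_only_ftab(pos, charge, exclusions = exclusions)
  out <- cpp_energy_forces(ftab, pos, matrix(0, 0, 3))
  list(energy = out$coulomb, forces = out$f_core)
}

#' Ewald energy and forces of a periodic set of point charges
#'
#' Real-space + reciprocal-space + self-term Ewald summation with parameters
#' auto-tuned from the accuracy target. A net-charged system is handled with
#' a uniform neutralizing background (with a warning).
#'
#' @inheritParams coulomb_direct
#' @param cell 3 x 3 lattice-vector rows (A).
#' @param accuracy dimensionless accuracy target.
#' @param rcut optional real-space cutoff (A).
#' @return list with `energy` (eV) and `forces` (n x 3, eV/A).
#' @export
ewald_energy_force <- function(pos, charge, cell, accuracy = 1e-6,
                               exclusions = NULL, rcut = NULL) {
  pos <- as_coord_matrix(pos, "pos")
  cell <- matrix(as.numeric(cell), 3, 3)
  if (abs(sum(charge)) > 1e-8)
    warning("non-neutral periodic system: applying neutralizing background")
  ftab <- charges_only_ftab(pos, charge, cell = cell, exclusions = exclusions,
                            accuracy = accuracy, rcut = rcut)
  out <- cpp_energy_forces(ftab, pos, matrix(0, 0, 3))
  list(energy = out$coulomb, forces = out$f_core)
}
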