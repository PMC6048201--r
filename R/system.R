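#' Create a particle system
#'
#' A `particle_system` holds the cores (physical atoms), the optional shells
#' attached to polarizable atoms in the core-shell (Drude) model, the bonded
#' topology and the periodic cell. Positions are in Angstrom, velocities in
#' Angstrom/fs, masses in amu and charges in e.
#'
#' Shells are stored in a parallel block: `shells$owner[k]` is the index of
#' the core that shell `k` is harmonically tethered to (spring constant
#' `shells$k[k]`, eV/A^2). Every shell has exactly one owner and a core owns
#' at most one shell.
#'
#' @param species character vector of element symbols, one per core.
#' @param pos n x 3 matrix of core positions (A).
#' @param mass core masses (amu).
#' @param charge core point charges (e).
#' @param vel n x 3 matrix of core velocities (A/fs); defaults to zero.
#' @param shells `NULL`, or a list with elements `owner` (integer), `pos`
#'   (ns x 3), `mass`, `charge`, `k` (spring constants, eV/A^2) and
#'   optionally `vel`.
#' @param bonds integer matrix (n_bonds x 2) of core indices.
#' @param angles integer matrix (n_angles x 3) of core indices, vertex in
#'   column 2.
#' @param cell `NULL` for an open (non-periodic) system, else a 3 x 3 matrix
#'   whose rows are the lattice vectors a, b, c (A).
#' @param qm_atoms integer indices of cores belonging to an embedded quantum
#'   region (excluded from the MM force field; see
#'   [embedding_energy_force()]).
#' @param molecule optional integer molecule index per core.
#' @return An object of class `particle_system`.
#' @seealso [decompose_pairs()], [attach_shells()], [build_crystal()]
#' @export
particle_system <- function(species, pos, mass, charge,
                            vel = NULL, shells = NULL,
                            bonds = NULL, angles = NULL, cell = NULL,
                            qm_atoms = integer(0), molecule = NULL) {
  pos <- as_coord_matrix(pos, "pos")
  n <- nrow(pos)
  stopifnot(length(species) == n, length(mass) == n, length(charge) == n)
  if (is.null(vel)) vel <- matrix(0, n, 3) else vel <- as_coord_matrix(vel, "vel")
  stopifnot(nrow(vel) == n)
  if (!is.null(cell)) {
    cell <- matrix(as.numeric(cell), 3, 3)
    if (abs(det(cell)) < 1e-10) stop("singular cell")
  }
  if (!is.null(bonds)) {
    bonds <- matrix(as.integer(bonds), ncol = 2)
  } else bonds <- matrix(integer(0), 0, 2)
  if (!is.null(angles)) {
    angles <- matrix(as.integer(angles), ncol = 3)
  } else angles <- matrix(integer(0), 0, 3)
  sys <- structure(list(
    species = as.character(species), pos = pos,
    mass = as.numeric(mass), charge = as.numeric(charge), vel = vel,
    shells = NULL, bonds = bonds, angles = angles, cell = cell,
    qm_atoms = as.integer(qm_atoms), molecule = molecule
  ), class = "particle_system")
  if (!is.null(shells)) sys <- set_shells(sys, shells)
  validate_system(sys)
  sys
}

as_coord_matrix <- function(x, what) {
  x <- matrix(as.numeric(x), ncol = 3)
  if (anyNA(x)) stop("non-finite values in ", what)
  x
}

set_shells <- function(sys, shells) {
  ns <- length(shells$owner)
  shells$owner <- as.integer(shells$owner)
  shells$pos <- as_coord_matrix(shells$pos, "shell pos")
  if (is.null(shells$vel)) shells$vel <- matrix(0, ns, 3)
  else shells$vel <- as_coord_matrix(shells$vel, "shell vel")
  shells$mass <- as.numeric(shells$mass)
  shells$charge <- as.numeric(shells$charge)
  shells$k <- as.numeric(shells$k)
  stopifnot(nrow(shells$pos) == ns, length(shells$mass) == ns,
            length(shells$charge) == ns, length(shells$k) == ns,
            nrow(shells$vel) == ns)
  sys$shells <- shells
  sys
}

validate_system <- function(sys) {
  n <- n_atoms(sys)
  if (n_shells(sys) > 0) {
    sh <- sys$shells
    if (any(sh$owner < 1L | sh$owner > n)) stop("shell with missing owner core")
    if (anyDuplicated(sh$owner)) stop("a core owns more than one shell")
    if (any(sh$mass <= 0)) stop("shell masses must be positive")
    if (any(sh$k <= 0)) stop("shell spring constants must be positive")
  }
  if (any(sys$mass <= 0)) stop("core masses must be positive")
  invisible(sys)
}

#' @rdname particle_system
#' @param sys a `particle_system`.
#' @export
n_atoms <- function(sys) nrow(sys$pos)

#' @rdname particle_system
#' @export
n_shells <- function(sys) if (is.null(sys$shells)) 0L else length(sys$shells$owner)

#' @rdname particle_system
#' @export
total_charge <- function(sys) {
  q <- sum(sys$charge)
  if (n_shells(sys) > 0) q <- q + sum(sys$shells$charge)
  q
}

#' Number of nuclear degrees of freedom
#'
#' N_f = 3 n_atoms minus any imposed momentum constraints. By default the
#' three centre-of-mass translations are removed for open (non-periodic)
#' systems and kept for periodic crystals.
#'
#' @param sys a `particle_system`.
#' @param remove_com `NULL` (default policy above) or logical.
#' @export
dof_count <- function(sys, remove_com = NULL) {
  if (is.null(remove_com)) remove_com <- is.null(sys$cell)
  3L * n_atoms(sys) - if (remove_com) 3L else 0L
}

#' @export
print.particle_system <- function(x, ...) {
  cat("particle_system:", n_atoms(x), "cores,", n_shells(x), "shells\n")
  tab <- table(x$species)
  cat("  composition:", paste(names(tab), as.integer(tab), collapse = " "), "\n")
  cat("  cell:", if (is.null(x$cell)) "open" else
    paste(signif(c(x$cell[1, 1], x$cell[2, 2], x$cell[3, 3]), 6), collapse = " x "), "\n")
  cat("  bonds:", nrow(x$bonds), " angles:", nrow(x$angles),
      " total charge:", signif(total_charge(x), 8), "\n")
  if (length(x$qm_atoms)) cat("  QM region:", length(x$qm_atoms), "atoms\n")
  invisible(x)
}

#' Minimum-image displacement
#'
#' Maps displacement vectors to their shortest periodic image. For an open
#' system (`cell = NULL`) the input is returned unchanged. General triclinic
#' cells are handled by wrapping the fractional coordinates and searching the
#' 27 neighbouring images.
#'
#' @param d displacement vector (length 3) or n x 3 matrix (A).
#' @param cell 3 x 3 matrix of lattice-vector rows, or `NULL`.
#' @return Same shape as `d`.
#' @examples
#' minimum_image(c(9.9, 0, 0), diag(10, 3))  # -> (-0.1, 0, 0)
#' @export
minimum_image <- function(d, cell = NULL) {
  if (is.null(cell)) return(d)
  vec <- is.null(dim(d))
  m <- if (vec) matrix(d, 1, 3) else d
  out <- cpp_minimum_image(m, cell)
  if (vec) drop(out) else out
}

#' Decompose core-shell pairs into centre-of-mass and relative coordinates
#'
#' For each core-shell pair (I, k): S_I = (M_I R_I + m_k r_k) / (M_I + m_k)
#' and s_k = R_I - r_k; velocities are transformed consistently. Bare cores
#' (atoms without a shell) pass through with S_I = R_I and pair mass M_I.
#' The spring extension of the shell-model energy is |s_k|.
#'
#' @param sys a `particle_system`.
#' @return A list of class `pair_decomposition` with elements `com_pos`,
#'   `com_vel` (n x 3), `pair_mass` (Mbar_I, amu), `rel_pos`, `rel_vel`
#'   (ns x 3), `red_mass` (mbar_k, amu), `owner` (shell -> core index) and
#'   `has_shell` (logical per core).
#' @seealso [recompose_pairs()], [transform_forces()]
#' @export
decompose_pairs <- function(sys) {
  n <- n_atoms(sys)
  ns <- n_shells(sys)
  com_pos <- sys$pos
  com_vel <- sys$vel
  pair_mass <- sys$mass
  has_shell <- logical(n)
  if (ns > 0) {
    sh <- sys$shells
    o <- sh$owner
    has_shell[o] <- TRUE
    Mbar <- sys$mass[o] + sh$mass
    pair_mass[o] <- Mbar
    w_core <- sys$mass[o] / Mbar
    w_shell <- sh$mass / Mbar
    com_pos[o, ] <- sys$pos[o, , drop = FALSE] * w_core + sh$pos * w_shell
    com_vel[o, ] <- sys$vel[o, , drop = FALSE] * w_core + sh$vel * w_shell
    rel_pos <- sys$pos[o, , drop = FALSE] - sh$pos
    rel_vel <- sys$vel[o, , drop = FALSE] - sh$vel
    red_mass <- sys$mass[o] * sh$mass / Mbar
  } else {
    rel_pos <- matrix(0, 0, 3); rel_vel <- matrix(0, 0, 3); red_mass <- numeric(0)
  }
  structure(list(com_pos = com_pos, com_vel = com_vel, pair_mass = pair_mass,
                 rel_pos = rel_pos, rel_vel = rel_vel, red_mass = red_mass,
                 owner = if (ns > 0) sys$shells$owner else integer(0),
                 has_shell = has_shell),
            class = "pair_decomposition")
}

#' Recompose Cartesian coordinates from a pair decomposition
#'
#' Inverse of [decompose_pairs()]: R_I = S_I + (m_k/Mbar_I) s_k and
#' r_k = S_I - (M_I/Mbar_I) s_k (same weights for velocities).
#'
#' @param sys a `particle_system` supplying masses/topology.
#' @param decomp a `pair_decomposition` (possibly with modified coordinates
#'   or velocities).
#' @return `sys` with core and shell positions/velocities replaced.
#' @export
recompose_pairs <- function(sys, decomp) {
  sys$pos <- decomp$com_pos
  sys$vel <- decomp$com_vel
  if (n_shells(sys) > 0) {
    sh <- sys$shells
    o <- sh$owner
    Mbar <- decomp$pair_mass[o]
    wm <- sh$mass / Mbar           # m_k / Mbar
    wM <- sys$mass[o] / Mbar       # M_I / Mbar
    sys$pos[o, ] <- decomp$com_pos[o, , drop = FALSE] + decomp$rel_pos * wm
    sys$vel[o, ] <- decomp$com_vel[o, , drop = FALSE] + decomp$rel_vel * wm
    sys$shells$pos <- decomp$com_pos[o, , drop = FALSE] - decomp$rel_pos * wM
    sys$shells$vel <- decomp$com_vel[o, , drop = FALSE] - decomp$rel_vel * wM
  }
  sys
}

#' Transform Cartesian forces to centre-of-mass / relative forces
#'
#' For a core-shell pair (I, k) with Cartesian forces F_I (core) and f_k
#' (shell): F^(S)_I = F_I + f_k and f^(s)_k = (m_k F_I - M_I f_k) / Mbar_I.
#' With these conventions Mbar S" = F^(S) and mbar s" = f^(s) reproduce the
#' Cartesian equations of motion exactly. Bare cores pass through.
#'
#' @param f_core n x 3 Cartesian forces on cores (eV/A).
#' @param f_shell ns x 3 Cartesian forces on shells (eV/A).
#' @param sys a `particle_system`.
#' @return list with `com` (n x 3) and `rel` (ns x 3) force matrices.
#' @export
transform_forces <- function(f_core, f_shell, sys) {
  n <- n_atoms(sys); ns <- n_shells(sys)
  f_core <- as_coord_matrix(f_core, "core forces")
  if (nrow(f_core) != n) stop("core force shape mismatch")
  com <- f_core
  if (ns > 0) {
    f_shell <- as_coord_matrix(f_shell, "shell forces")
    if (nrow(f_shell) != ns) stop("shell force shape mismatch")
    sh <- sys$shells
    o <- sh$owner
    Mbar <- sys$mass[o] + sh$mass
    com[o, ] <- com[o, , drop = FALSE] + f_shell
    rel <- (f_core[o, , drop = FALSE] * sh$mass - f_shell * sys$mass[o]) / Mbar
  } else rel <- matrix(0, 0, 3)
  list(com = com, rel = rel)
}

#' Kinetic energies of a system (eV)
#'
#' Returns the Cartesian kinetic energies of cores and shells and the
#' equivalent centre-of-mass / relative partition, which are equal by
#' construction of the pair transform.
#'
#' @param sys a `particle_system`.
#' @return list with `core`, `shell`, `com`, `rel` (all eV).
#' @export
kinetic_energies <- function(sys) {
  ke <- function(m, v) 0.5 * .MV2E * sum(m * rowSums(v * v))
  d <- decompose_pairs(sys)
  list(core = ke(sys$mass, sys$vel),
       shell = if (n_shells(sys) > 0) ke(sys$shells$mass, sys$shells$vel) else 0,
       com = ke(d$pair_mass, d$com_vel),
       rel = if (n_shells(sys) > 0) ke(d$red_mass, d$rel_vel) else 0)
}

#' Remove total linear momentum
#'
#' Subtracts the centre-of-mass velocity (over cores and shells) so the total
#' linear momentum vanishes. Applied once at velocity initialisation.
#'
#' @param sys a `particle_system`.
#' @export
remove_com_momentum <- function(sys) {
  m <- sys$mass; p <- colSums(sys$vel * m)
  mtot <- sum(m)
  if (n_shells(sys) > 0) {
    p <- p + colSums(sys$shells$vel * sys$shells$mass)
    mtot <- mtot + sum(sys$shells$mass)
  }
  vcm <- p / mtot
  sys$vel <- sweep(sys$vel, 2, vcm)
  if (n_shells(sys) > 0) sys$shells$vel <- sweep(sys$shells$vel, 2, vcm)
  sys
}
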