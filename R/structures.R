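# Deterministic builders for the test systems: silica polymorph supercells,
# oxygen vacancies and polarizable water clusters.

# Conventional-cell constants and fractional coordinates from standard
# crystallographic refinements:
#  - alpha-cristobalite: P4_1 2_1 2, a = 4.9717 A, c = 6.9223 A,
#    Si 4a (u, u, 0) with u = 0.3047; O 8b (0.2381, 0.1109, 0.1826)
#    (Downs & Palmer refinement).
#  - alpha-quartz: P3_2 21, a = 4.916 A, c = 5.4054 A, Si u = 0.4697,
#    O (0.4133, 0.2672, 0.1188) (Levien et al. refinement).
# These are bundled fixtures, not downloads.
crystal_data <- function(polymorph) {
  if (polymorph == "alpha_cristobalite") {
    a <- 4.9717; c0 <- 6.9223
    u <- 0.3047
    si <- rbind(c(u, u, 0), c(-u, -u, 0.5),
                c(0.5 - u, 0.5 + u, 0.25), c(0.5 + u, 0.5 - u, 0.75))
    x <- 0.2381; y <- 0.1109; z <- 0.1826
    o <- rbind(c(x, y, z), c(-x, -y, z + 0.5),
               c(0.5 - y, 0.5 + x, z + 0.25), c(0.5 + y, 0.5 - x, z + 0.75),
               c(0.5 - x, 0.5 + y, 0.25 - z), c(0.5 + x, 0.5 - y, 0.75 - z),
               c(y, x, -z), c(-y, -x, 0.5 - z))
    cell <- diag(c(a, a, c0))
  } else if (polymorph == "alpha_quartz") {
    a <- 4.916; c0 <- 5.4054
    u <- 0.4697
    x <- 0.4133; y <- 0.2672; z <- 0.2144
    # P3_1 21 orbits (Si 3a, O 6c); gives the two distinct Si-O bond
    # lengths (1.606 / 1.613 A) and full 4:2 connectivity
    si <- rbind(c(u, 0, 1 / 3), c(0, u, 2 / 3), c(-u, -u, 0))
    o <- rbind(c(x, y, z),
               c(-y, x - y, z + 1 / 3),
               c(y - x, -x, z + 2 / 3),
               c(y, x, -z),
               c(x - y, -y, 2 / 3 - z),
               c(-x, y - x, 1 / 3 - z))
    cell <- rbind(c(a, 0, 0), c(-a / 2, a * sqrt(3) / 2, 0), c(0, 0, c0))
  } else stop("unknown polymorph: ", polymorph)
  frac <- rbind(si, o) %% 1
  list(cell = cell, frac = frac,
       species = c(rep("Si", nrow(si)), rep("O", nrow(o))))
}

atomic_masses <- c(Si = 28.0855, O = 15.999, H = 1.008)

#' Build a silica polymorph supercell
#'
#' Places Si/O cores on the bundled conventional-cell lattice sites of
#' alpha-quartz (3 SiO2 per cell) or alpha-cristobalite (4 SiO2 per cell),
#' replicates the cell, assigns point charges from the force field, and
#' auto-detects the Si-O bond and O-Si-O / Si-O-Si angle topology by a
#' distance cutoff.
#'
#' @param polymorph `"alpha_cristobalite"` or `"alpha_quartz"`.
#' @param replication integer vector (na, nb, nc), each >= 1.
#' @param ff a `forcefield` supplying core charges (default [load_pmzhb()]).
#' @param bond_cutoff Si-O bond detection cutoff (A), default 2.0.
#' @param topology detect bonds and angles (default TRUE); skip for large
#'   supercells where only the lattice is needed.
#' @return A periodic `particle_system` (cores only; see [attach_shells()]).
#' @examples
#' sys <- build_crystal("alpha_cristobalite", c(1, 1, 1))
#' table(sys$species)  # 4 Si, 8 O
#' @export
build_crystal <- function(polymorph = c("alpha_cristobalite", "alpha_quartz"),
                          replication = c(1, 1, 1), ff = load_pmzhb(),
                          bond_cutoff = 2.0, topology = TRUE) {
  polymorph <- match.arg(polymorph)
  rep3 <- as.integer(replication)
  if (length(rep3) == 1) rep3 <- rep(rep3, 3)
  if (any(rep3 < 1)) stop("replication must be >= 1 in each direction")
  cd <- crystal_data(polymorph)
  shifts <- as.matrix(expand.grid(0:(rep3[1] - 1), 0:(rep3[2] - 1), 0:(rep3[3] - 1)))
  nuc <- nrow(cd$frac)
  frac <- matrix(0, nuc * nrow(shifts), 3)
  species <- character(nuc * nrow(shifts))
  for (s in seq_len(nrow(shifts))) {
    idx <- (s - 1) * nuc + seq_len(nuc)
    frac[idx, ] <- sweep(cd$frac, 2, shifts[s, ], "+")
    species[idx] <- cd$species
  }
  frac <- sweep(frac, 2, rep3, "/")
  cell <- cd$cell * rep3  # row-wise scaling of lattice vectors
  pos <- frac %*% cell
  charge <- vapply(species, function(sp) ff_total_charge(ff, sp), 0)
  mass <- unname(atomic_masses[species])
  sys <- particle_system(species, pos, mass, unname(charge), cell = cell)
  if (!topology) return(sys)
  detect_topology(sys, cutoff = bond_cutoff)
}

#' Read a CIF-like fractional-coordinate table
#'
#' Minimal parser for user-supplied cells: `key = value` lines for the cell
#' parameters (`a`, `b`, `c` in A and `alpha`, `beta`, `gamma` in degrees,
#' or `cell_length_a` etc. in CIF spelling), then a loop of
#' `species fx fy fz` rows (one site per line, fractional coordinates).
#' Charges are taken from the force field's total atomic charges and masses
#' from the bundled element table.
#'
#' @param path file path.
#' @param ff a `forcefield` supplying charges (default [load_pmzhb()]).
#' @param topology detect bonds/angles after building (default TRUE).
#' @param bond_cutoff bond detection cutoff (A).
#' @return A periodic `particle_system`.
#' @export
read_fractional <- function(path, ff = load_pmzhb(), topology = TRUE,
                            bond_cutoff = 2.0) {
  lines <- trimws(sub("#.*$", "", readLines(path)))
  lines <- lines[nzchar(lines)]
  par <- list()
  rows <- list()
  for (ln in lines) {
    if (grepl("=", ln)) {
      kv <- strsplit(ln, "\\s*=\\s*")[[1]]
      key <- sub("^_?cell_(length|angle)_", "", tolower(kv[1]))
      par[[key]] <- as.numeric(kv[2])
    } else {
      toks <- strsplit(ln, "\\s+")[[1]]
      if (length(toks) >= 4) rows[[length(rows) + 1]] <- toks[1:4]
    }
  }
  for (k in c("a", "b", "c")) if (is.null(par[[k]]))
    stop("fractional input missing cell parameter '", k, "'")
  alpha <- (par$alpha %||% 90) * pi / 180
  beta <- (par$beta %||% 90) * pi / 180
  gamma <- (par$gamma %||% 90) * pi / 180
  # standard crystallographic cell matrix (rows = lattice vectors)
  a <- par$a; b <- par$b; c0 <- par$c
  cx <- c0 * cos(beta)
  cy <- c0 * (cos(alpha) - cos(beta) * cos(gamma)) / sin(gamma)
  cz <- sqrt(c0^2 - cx^2 - cy^2)
  cell <- rbind(c(a, 0, 0),
                c(b * cos(gamma), b * sin(gamma), 0),
                c(cx, cy, cz))
  if (!length(rows)) stop("fractional input contains no coordinate rows")
  m <- do.call(rbind, rows)
  species <- m[, 1]
  frac <- matrix(as.numeric(m[, 2:4]), ncol = 3) %% 1
  pos <- frac %*% cell
  charge <- vapply(species, function(sp) ff_total_charge(ff, sp), 0)
  mass <- atomic_masses[species]
  if (anyNA(mass)) stop("unknown species in fractional input: ",
                        paste(unique(species[is.na(mass)]), collapse = ", "))
  sys <- particle_system(species, pos, unname(mass), unname(charge), cell = cell)
  if (topology) sys <- detect_topology(sys, cutoff = bond_cutoff)
  sys
}

#' Detect bonds and angles by distance cutoff
#'
#' Si-O (or generally hetero-species) contacts closer than `cutoff` under
#' the minimum image become bonds; angles are enumerated from all bond pairs
#' sharing a vertex.
#'
#' @param sys a `particle_system`.
#' @param cutoff bond detection cutoff (A).
#' @param pairs optional 2-column character matrix of bondable species pairs;
#'   default Si-O only when both present, else all pairs.
#' @return `sys` with `bonds` and `angles` filled in.
#' @export
detect_topology <- function(sys, cutoff = 2.0, pairs = NULL) {
  n <- n_atoms(sys)
  if (is.null(pairs)) {
    pairs <- if (all(c("Si", "O") %in% sys$species)) cbind("Si", "O")
             else as.matrix(expand.grid(unique(sys$species), unique(sys$species)))
  }
  ok_pair <- function(s1, s2)
    any((pairs[, 1] == s1 & pairs[, 2] == s2) | (pairs[, 1] == s2 & pairs[, 2] == s1))
  bonds <- list()
  # block over atoms to keep memory bounded for large supercells
  block <- 2000L
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    for (i in idx) {
      js <- (i + 1L):n
      if (i == n) next
      d <- sweep(sys$pos[js, , drop = FALSE], 2, sys$pos[i, ])
      d <- minimum_image(d, sys$cell)
      r2 <- rowSums(d * d)
      hit <- js[r2 < cutoff^2]
      for (j in hit) if (ok_pair(sys$species[i], sys$species[j]))
        bonds[[length(bonds) + 1L]] <- c(i, j)
    }
  }
  bonds <- if (length(bonds)) do.call(rbind, bonds) else matrix(integer(0), 0, 2)
  sys$bonds <- bonds
  sys$angles <- angles_from_bonds(bonds)
  sys
}

angles_from_bonds <- function(bonds) {
  if (nrow(bonds) == 0) return(matrix(integer(0), 0, 3))
  nb <- split(c(bonds[, 2], bonds[, 1]), c(bonds[, 1], bonds[, 2]))
  out <- list()
  for (v in names(nb)) {
    nbr <- sort(unique(nb[[v]]))
    if (length(nbr) < 2) next
    cmb <- utils::combn(nbr, 2)
    for (cidx in seq_len(ncol(cmb)))
      out[[length(out) + 1L]] <- c(cmb[1, cidx], as.integer(v), cmb[2, cidx])
  }
  if (length(out)) do.call(rbind, out) else matrix(integer(0), 0, 3)
}

#' Attach shells to the polarizable atoms of a system
#'
#' Adds one shell per atom of each shelled species declared by the force
#' field (p-MZHB: O only), placed exactly at the core position with zero
#' relative velocity. The atom's point charge is split into the core and
#' shell values of the force-field charge table, and the fictitious shell
#' mass is taken out of the core mass (standard Drude convention), so both
#' the total charge and the total mass of each atom are unchanged and the
#' core-shell pair's centre of mass carries exactly the atomic mass.
#'
#' @param sys a `particle_system` without shells.
#' @param ff a `forcefield`.
#' @param shell_mass fictitious shell mass (amu), default 0.2.
#' @return `sys` with the shell block attached.
#' @export
attach_shells <- function(sys, ff, shell_mass = 0.2) {
  if (n_shells(sys) > 0) stop("system already has shells")
  if (shell_mass <= 0) stop("shell mass must be positive")
  sp <- shelled_species(ff)
  owner <- which(sys$species %in% sp & !(seq_len(n_atoms(sys)) %in% sys$qm_atoms))
  if (!length(owner)) return(sys)
  kappa <- q_core <- q_shell <- numeric(length(owner))
  for (i in seq_along(owner)) {
    s <- sys$species[owner[i]]
    kappa[i] <- ff$springs$kappa[match(s, ff$springs$species)]
    q_core[i] <- ff_charge(ff, s, "core")
    q_shell[i] <- ff_charge(ff, s, "shell")
  }
  sys$charge[owner] <- q_core
  if (any(sys$mass[owner] <= shell_mass))
    stop("shell mass must be smaller than the atomic mass")
  sys$mass[owner] <- sys$mass[owner] - shell_mass
  set_shells(sys, list(owner = owner, pos = sys$pos[owner, , drop = FALSE],
                       mass = rep(shell_mass, length(owner)),
                       charge = q_shell, k = kappa))
}

#' Create an oxygen vacancy
#'
#' Removes an O core together with its shell, prunes all bonds and angles
#' involving it, and records the pair of Si atoms formerly bonded to the
#' removed O as the defect pair for Si-Si distance analysis.
#'
#' @param sys a `particle_system` (silica with topology).
#' @param site_index index of the O core to remove.
#' @return The reduced system, with `defect_si_pair` set (indices in the new
#'   numbering) and a `composition` note.
#' @export
create_oxygen_vacancy <- function(sys, site_index) {
  if (sys$species[site_index] != "O") stop("vacancy site must be an O core")
  n <- n_atoms(sys)
  partners <- unique(c(sys$bonds[sys$bonds[, 1] == site_index, 2],
                       sys$bonds[sys$bonds[, 2] == site_index, 1]))
  partners <- partners[sys$species[partners] == "Si"]
  keep <- setdiff(seq_len(n), site_index)
  remap <- integer(n); remap[keep] <- seq_along(keep)
  prune <- function(m) {
    if (nrow(m) == 0) return(m)
    m <- m[rowSums(m == site_index) == 0, , drop = FALSE]
    matrix(remap[m], ncol = ncol(m))
  }
  sys$species <- sys$species[keep]
  sys$pos <- sys$pos[keep, , drop = FALSE]
  sys$vel <- sys$vel[keep, , drop = FALSE]
  sys$mass <- sys$mass[keep]
  sys$charge <- sys$charge[keep]
  sys$bonds <- prune(sys$bonds)
  sys$angles <- prune(sys$angles)
  if (n_shells(sys) > 0) {
    sh <- sys$shells
    drop_k <- which(sh$owner == site_index)
    keep_k <- setdiff(seq_along(sh$owner), drop_k)
    sys$shells <- list(owner = remap[sh$owner[keep_k]],
                       pos = sh$pos[keep_k, , drop = FALSE],
                       vel = sh$vel[keep_k, , drop = FALSE],
                       mass = sh$mass[keep_k], charge = sh$charge[keep_k],
                       k = sh$k[keep_k])
  }
  if (!is.null(sys$molecule)) sys$molecule <- sys$molecule[keep]
  sys$defect_si_pair <- remap[partners]
  sys$composition <- table(sys$species)
  validate_system(sys)
  sys
}

#' Build a cluster of polarizable water molecules
#'
#' Places `n` water monomers at the equilibrium geometry of the bundled
#' polarizable water model ([load_water_ff()]), with random positions and
#' orientations subject to a minimum O-O separation, shells on the oxygens,
#' and deterministic output for a given seed.
#'
#' @param n number of molecules (>= 1).
#' @param seed integer seed.
#' @param ff water force field (default [load_water_ff()]).
#' @param shell_mass fictitious shell mass (amu).
#' @param min_oo minimum O-O separation between molecules (A), default 2.6.
#' @param spread radius of the placement sphere (A); grows automatically if
#'   placement fails.
#' @return An open `particle_system` with 3n cores, n shells, and a
#'   `molecule` index.
#' @export
build_water_cluster <- function(n, seed = 1, ff = load_water_ff(),
                                shell_mass = 0.2, min_oo = 2.6, spread = 2.8) {
  if (n < 1) stop("n must be >= 1")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  rng <- function(k) stats::runif(k)
  r0 <- ff$bonds$r0[1]; th0 <- ff$angles$theta0[1] * pi / 180
  monomer <- rbind(c(0, 0, 0),
                   c(r0, 0, 0),
                   c(r0 * cos(th0), r0 * sin(th0), 0))  # O, H, H
  rand_rot <- function() {
    # uniform random rotation from a normalized quaternion
    u <- rng(4) * 2 - 1
    while (sum(u^2) < 1e-8) u <- rng(4) * 2 - 1
    u <- u / sqrt(sum(u^2))
    a <- u[1]; b <- u[2]; c2 <- u[3]; d <- u[4]
    rbind(c(a*a+b*b-c2*c2-d*d, 2*(b*c2-a*d), 2*(b*d+a*c2)),
          c(2*(b*c2+a*d), a*a-b*b+c2*c2-d*d, 2*(c2*d-a*b)),
          c(2*(b*d-a*c2), 2*(c2*d+a*b), a*a-b*b-c2*c2+d*d))
  }
  o_sites <- matrix(0, 0, 3)
  pos <- NULL
  for (mol in seq_len(n)) {
    placed <- FALSE
    for (try in 1:500) {
      centre <- if (mol == 1) c(0, 0, 0) else (rng(3) * 2 - 1) * spread
      if (mol > 1 && nrow(o_sites) > 0) {
        d2 <- rowSums(sweep(o_sites, 2, centre)^2)
        if (min(d2) < min_oo^2) { if (try %% 100 == 0) spread <- spread * 1.15; next }
      }
      placed <- TRUE
      break
    }
    if (!placed) stop("water placement failed after retries")
    m <- monomer %*% t(rand_rot())
    m <- sweep(m, 2, centre, "+")
    o_sites <- rbind(o_sites, m[1, ])
    pos <- rbind(pos, m)
  }
  species <- rep(c("O", "H", "H"), n)
  molecule <- rep(seq_len(n), each = 3)
  charge <- vapply(species, function(sp) ff_total_charge(ff, sp), 0)
  mass <- unname(atomic_masses[species])
  oi <- which(species == "O")
  bonds <- do.call(rbind, lapply(oi, function(i) rbind(c(i, i + 1L), c(i, i + 2L))))
  angles <- do.call(rbind, lapply(oi, function(i) c(i + 1L, i, i + 2L)))
  sys <- particle_system(species, pos, mass, unname(charge),
                         bonds = bonds, angles = angles, molecule = molecule)
  attach_shells(sys, ff, shell_mass = shell_mass)
}
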