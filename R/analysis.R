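# Trajectory observables: structural averages, defect geometry, drift
# estimation, temperature statistics, vacancy formation energy.

frames_of <- function(run) {
  if (inherits(run, "md_run")) run$frames else run
}

# bonds of the requested species pair, as an index matrix
select_bonds <- function(sys, species_pair) {
  b <- sys$bonds
  if (nrow(b) == 0) stop("system has no bond topology")
  s1 <- sys$species[b[, 1]]; s2 <- sys$species[b[, 2]]
  hit <- (s1 == species_pair[1] & s2 == species_pair[2]) |
         (s1 == species_pair[2] & s2 == species_pair[1])
  if (!any(hit)) stop("no bonds match species pair ",
                      paste(species_pair, collapse = "-"))
  b[hit, , drop = FALSE]
}

select_angles <- function(sys, species_triple) {
  a <- sys$angles
  if (nrow(a) == 0) stop("system has no angle topology")
  s1 <- sys$species[a[, 1]]; s2 <- sys$species[a[, 2]]; s3 <- sys$species[a[, 3]]
  hit <- s2 == species_triple[2] &
    ((s1 == species_triple[1] & s3 == species_triple[3]) |
     (s1 == species_triple[3] & s3 == species_triple[1]))
  if (!any(hit)) stop("no angles match species triple ",
                      paste(species_triple, collapse = "-"))
  a[hit, , drop = FALSE]
}

sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

production_frames <- function(run, discard = 0.2) {
  fr <- frames_of(run)
  if (!length(fr)) stop("no frames recorded")
  keep <- seq_len(length(fr))
  drop_n <- floor(discard * length(fr))
  if (drop_n > 0) keep <- keep[-(seq_len(drop_n))]
  fr[keep]
}

#' Mean bond length over a trajectory
#'
#' Averages the minimum-image core-core distances of all bonds matching the
#' species pair over the production frames (geometry statistics use the
#' core positions: in the shell model the physical atom positions are the
#' cores'). The spread is the population standard deviation over all bonds
#' and frames.
#'
#' @param run an `md_run` with frames, or a plain list of frames.
#' @param species_pair character pair, default c("Si", "O").
#' @param sys template `particle_system` (default `run$sys`) supplying
#'   topology and cell.
#' @param discard fraction of initial frames discarded as equilibration
#'   (default 0.2; set 0 if the frames are already production-only).
#' @return list with `mean`, `sd` (A) and the per-sample `values`.
#' @export
mean_bond_length <- function(run, species_pair = c("Si", "O"), sys = NULL,
                             discard = 0.2) {
  sys <- sys %||% run$sys
  b <- select_bonds(sys, species_pair)
  fr <- production_frames(run, discard)
  vals <- unlist(lapply(fr, function(f) {
    d <- f$pos[b[, 1], , drop = FALSE] - f$pos[b[, 2], , drop = FALSE]
    d <- minimum_image(d, sys$cell)
    sqrt(rowSums(d * d))
  }))
  list(mean = mean(vals), sd = sd_pop(vals), values = vals)
}

#' Mean angle over a trajectory
#'
#' @inheritParams mean_bond_length
#' @param species_triple character triple (vertex in the middle), e.g.
#'   c("O", "Si", "O") or c("Si", "O", "Si").
#' @return list with `mean`, `sd` (degrees) and `values`.
#' @export
mean_angle <- function(run, species_triple = c("O", "Si", "O"), sys = NULL,
                       discard = 0.2) {
  sys <- sys %||% run$sys
  a <- select_angles(sys, species_triple)
  fr <- production_frames(run, discard)
  vals <- unlist(lapply(fr, function(f) {
    u <- minimum_image(f$pos[a[, 1], , drop = FALSE] - f$pos[a[, 2], , drop = FALSE], sys$cell)
    v <- minimum_image(f$pos[a[, 3], , drop = FALSE] - f$pos[a[, 2], , drop = FALSE], sys$cell)
    ct <- rowSums(u * v) / sqrt(rowSums(u * u) * rowSums(v * v))
    acos(pmax(-1, pmin(1, ct))) * 180 / pi
  }))
  list(mean = mean(vals), sd = sd_pop(vals), values = vals)
}

#' Defect Si-Si distance distribution
#'
#' Per-frame minimum-image distance between the two Si atoms flanking an
#' oxygen vacancy (recorded by [create_oxygen_vacancy()]).
#'
#' @inheritParams mean_bond_length
#' @param si_pair index pair (default `sys$defect_si_pair`).
#' @param breaks histogram breaks (passed to [hist()]).
#' @return list with `values`, `mean`, `sd`, `histogram`.
#' @export
defect_distance_distribution <- function(run, si_pair = NULL, sys = NULL,
                                         discard = 0.2, breaks = 30) {
  sys <- sys %||% run$sys
  si_pair <- si_pair %||% sys$defect_si_pair
  if (is.null(si_pair) || length(si_pair) != 2)
    stop("no defect Si pair recorded in this system")
  fr <- production_frames(run, discard)
  vals <- vapply(fr, function(f) {
    d <- minimum_image(f$pos[si_pair[1], ] - f$pos[si_pair[2], ], sys$cell)
    sqrt(sum(d * d))
  }, 0)
  h <- graphics::hist(vals, breaks = breaks, plot = FALSE)
  list(values = vals, mean = mean(vals), sd = sd_pop(vals), histogram = h)
}

#' Energy drift of a time series
#'
#' Least-squares slope of total energy versus time, normalised per atom and
#' per ps, reported both in eV and in Hartree atomic units (the convention
#' used for conservation benchmarks).
#'
#' @param time_fs time axis (fs), >= 100 samples recommended.
#' @param energy_eV total (or conserved) energy series (eV).
#' @param n_atoms number of atoms used for normalisation.
#' @return list with `au_per_atom_ps`, `ev_per_atom_ps`, `slope_ev_per_fs`.
#' @export
energy_drift <- function(time_fs, energy_eV, n_atoms) {
  if (length(time_fs) < 2 || diff(range(time_fs)) == 0)
    stop("degenerate time axis")
  fit <- stats::lm.fit(cbind(1, time_fs), energy_eV)
  slope <- fit$coefficients[2]           # eV / fs
  ev_atom_ps <- slope * 1000 / n_atoms
  list(au_per_atom_ps = unname(ev_atom_ps / .HARTREE),
       ev_per_atom_ps = unname(ev_atom_ps),
       slope_ev_per_fs = unname(slope))
}

#' Oxygen vacancy formation energy
#'
#' Pure formula on user-supplied component energies:
#' dE_f = (x/2) (E(O2) + E_diss(O2)) + E(SiO_{2-x}) - E(SiO2), with the O2
#' dissociation energy defaulting to the experimental 5.16 eV.
#'
#' @param e_o2 energy of the O2 molecule (eV).
#' @param e_defect energy of the defective supercell (eV).
#' @param e_bulk energy of the pristine supercell (eV).
#' @param x number of removed O atoms (dimensionless).
#' @param e_diss O2 dissociation energy (eV), default 5.16.
#' @return formation energy (eV).
#' @examples
#' vacancy_formation_energy(-10, e_defect = 11.15, e_bulk = 0, x = 1)  # 8.73
#' @export
vacancy_formation_energy <- function(e_o2, e_defect, e_bulk, x = 1,
                                     e_diss = 5.16) {
  (x / 2) * (e_o2 + e_diss) + e_defect - e_bulk
}

#' Temperature statistics of an NVT run
#'
#' Means, spreads and histograms of the physical and shell temperature
#' series, plus the canonical relative variance expected for T_phys
#' (var(T)/<T>^2 = 2/N_f for a canonical ensemble).
#'
#' @param run an `md_run`, or a data.frame with columns `T_phys_K`,
#'   `T_s_K`.
#' @param discard fraction of initial records discarded.
#' @param breaks histogram breaks.
#' @return list with `T_phys` and `T_s` sublists (`mean`, `sd`,
#'   `histogram`) and `canonical_rel_var` when N_f is known.
#' @export
temperature_statistics <- function(run, discard = 0.2, breaks = 30) {
  s <- if (inherits(run, "md_run")) run$series else run
  keep <- seq_len(nrow(s))
  drop_n <- floor(discard * nrow(s))
  if (drop_n > 0) keep <- keep[-(seq_len(drop_n))]
  s <- s[keep, , drop = FALSE]
  one <- function(x) {
    x <- x[is.finite(x)]
    if (!length(x)) return(NULL)
    list(mean = mean(x), sd = sd_pop(x),
         histogram = graphics::hist(x, breaks = breaks, plot = FALSE))
  }
  out <- list(T_phys = one(s$T_phys_K), T_s = one(s$T_s_K))
  if (inherits(run, "md_run")) out$canonical_rel_var <- 2 / run$nf
  out
}
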