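# shellmd — extended-Lagrangian core–shell polarizable molecular dynamics

`shellmd` is an R package for molecular dynamics with the core–shell
(Drude) polarizable force-field model, aimed at simulators who want
explicit electronic polarization in ionic/covalent materials — silica
frameworks in particular — without minimizing the shell positions at every
step, plus an electrostatic-embedding layer for coupling a quantum-region
surrogate to the polarizable MM environment.

## The method

A polarizable atom is a core (mass $M_I$, charge $q_I^c$) plus a shell
(fictitious mass $m_k$, charge $q_k^s$) bound by a harmonic spring
$\tfrac12 \kappa_k s_k^2$ with $s_k = |\mathbf{R}_I - \mathbf{r}_k|$; the
induced dipole is the shell displacement times the shell charge. The
shells are *extended dynamical variables*: they are propagated classically
with a small fictitious mass and kept adiabatically cold instead of being
relaxed each step. Each pair is monitored in centre-of-mass/relative
coordinates with two kinetic temperatures,

$$T_\mathrm{phys} = \frac{1}{N_f k_B}\sum_I \bar M_I \dot{\mathbf S}_I^2,
\qquad
T_s = \frac{1}{3 n_s k_B}\sum_k \bar m_k \dot{\mathbf s}_k^2,$$

and two Nosé–Hoover chains act on exactly those coordinates: the nuclear
chain holds $T_\mathrm{phys}$ at its target (300 K in the benchmarks)
while the shell chain pins $T_s$ near 0 K (1 K target). A third chain can
thermostat the internal polarization variables of an embedded
quantum-region surrogate, completing the three-subsystem
extended-Lagrangian architecture. The package bundles **p-MZHB**, a
low-point-charge polarizable silica force field (harmonic Si–O bonds and
O–Si–O / Si–O–Si angles, 12-6 dispersion, O cores at $+1.387258$ e with
shells at $-1.737258$ e — summing to $-0.35$ e against Si at $+0.70$ e —
and $\kappa_O = 99.4732$ eV/Å²), silica polymorph and water-cluster
builders, Ewald electrostatics over all core and shell sites, and
trajectory analysis (structural averages, drift estimation, temperature
statistics, oxygen-vacancy formation energies).

See the methods vignette (`vignettes/shell-model-dynamics.Rmd`) for the
full model, parameter defaults and numerical choices.

## A worked example

Five polarizable water molecules (bundled stand-in model), NVE at
dt = 0.1 fs for 2 ps:

```r
library(shellmd)

ff  <- load_water_ff()
sys <- build_water_cluster(5, seed = 7)           # 15 cores + 5 O shells
sys <- initialize_velocities(sys, 300, seed = 1)  # MB on COM coords, cold shells
run <- run_md(sys, ff, integrator_config(timestep = 0.1), 20000)

s  <- run$series
energy_drift(s$time_fs, s$e_total_eV, n_atoms(sys))$au_per_atom_ps
#> [1] 2.73e-09           # total-energy drift, Hartree / atom / ps
mean(s$T_s_K)
#> [1] 11.6               # shells stay far colder than the ~590 K nuclei
```

The drift of order $10^{-9}$ a.u. atom⁻¹ ps⁻¹ says the extended-Lagrangian
propagation conserves the total energy of nuclei + shells essentially to
integrator accuracy. The as-built cluster relaxes violently (the nuclei
heat to ~590 K), yet the shells stay an order of magnitude colder — the
adiabatic decoupling that keeps them near the polarization-response
surface; a thermostated production run pins them at ~1 K.

For the silica benchmark, the bundled configuration runs the full
pipeline (build → minimize shells → equilibrate → production NVT →
structural averages):

```r
cfg <- system.file("configs", "cristobalite_nvt_300K.yml", package = "shellmd")
res <- run_experiment(cfg, seed = 1)
res$summary$mean_SiO_A       # 1.602 Å   (Si–O bond)
res$summary$mean_OSiO_deg    # 109.4°    (tetrahedral angle)
res$summary$mean_SiOSi_deg   # 145.0°    (inter-tetrahedral angle)
```

A thin command-line front end with `build`, `minimize`, `md`, `analyze`
and `run` subcommands is installed at `inst/cli/shellmd`.

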