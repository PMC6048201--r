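---
title: "Extended-Lagrangian core-shell dynamics: model, thermostats, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extended-Lagrangian core-shell dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`shellmd` implements polarizable molecular dynamics with the core-shell
(Drude) model. A polarizable atom is split into a charged core of mass
$M_I$ at $\mathbf{R}_I$ and a charged shell of small fictitious mass $m_k$
at $\mathbf{r}_k$, tethered harmonically with stiffness $\kappa_k$. The MM
energy is

$$E_\mathrm{MM} = E_b + E_\mathrm{nb} + \sum_k \tfrac12 \kappa_k s_k^2,
\qquad s_k = |\mathbf{R}_I - \mathbf{r}_k|,$$

where the bonded terms $E_b$ (harmonic bonds and angles) and the dispersion
part of $E_\mathrm{nb}$ are evaluated at the shell position for atoms that
own a shell, while the electrostatics runs over every core and shell point
charge. The induced dipole of an atom is the shell displacement times the
shell charge, so polarization emerges from the force balance between the
spring and the local electric field.

Rather than minimizing the shell positions at every step, the shells are
*extended degrees of freedom*: they carry a small fictitious mass and are
propagated classically alongside the nuclei. The scheme works only if the
shell subsystem stays adiabatically decoupled from the hot nuclei — cold
shells track the minimized (Born-Oppenheimer-like) surface. Concretely,
each core-shell pair is transformed to centre-of-mass and relative
coordinates,

$$\mathbf{S}_I = \frac{M_I \mathbf{R}_I + m_k \mathbf{r}_k}{M_I + m_k},
\qquad \mathbf{s}_k = \mathbf{R}_I - \mathbf{r}_k,$$

with pair mass $\bar M_I = M_I + m_k$ and reduced mass
$\bar m_k = M_I m_k / \bar M_I$, and two kinetic temperatures are tracked:

$$T_\mathrm{phys} = \frac{1}{N_f k_B} \sum_I \bar M_I \dot{\mathbf{S}}_I^2,
\qquad
T_s = \frac{1}{3 n_s k_B} \sum_k \bar m_k \dot{\mathbf{s}}_k^2 .$$

$T_\mathrm{phys}$ is the physical temperature of the nuclei;
$T_s$ measures the heat content of the fictitious relative motion and must
stay near zero. Forces transform as
$\mathbf{F}^{(S)}_I = \mathbf{F}_I + \mathbf{f}_k$ and
$\mathbf{f}^{(s)}_k = (m_k \mathbf{F}_I - M_I \mathbf{f}_k)/\bar M_I$, so
that $\bar M \ddot{\mathbf{S}} = \mathbf{F}^{(S)}$ and
$\bar m \ddot{\mathbf{s}} = \mathbf{f}^{(s)}$ reproduce the Cartesian
equations of motion exactly; the test suite verifies the two propagation
routes agree to $10^{-9}$ Å over hundreds of steps.

## Thermostats

NVT sampling uses Nosé-Hoover chains (length 4 by default, propagated with
a 7-point Suzuki-Yoshida factorization on either side of the velocity-Verlet
update). Crucially, the chains act on the *transformed* coordinates:

* a nuclear chain couples to the centre-of-mass velocities against
  $N_f k_B T_\mathrm{phys}$ (default 300 K, $\tau = 50$ fs),
* a shell chain couples to the relative velocities against
  $3 n_s k_B T_s$ (default 1 K, $\tau = 10$ fs — slow enough that the
  chain's own integration error stays well below the conserved-quantity
  drift bound, fast enough to hold the shells at their kelvin-scale
  target), and
* an optional third chain couples to the surrogate's internal polarization
  variables (below); its control variable is a kinetic-energy target
  (0.0007 Hartree by default), mapped onto an equivalent chain temperature
  via $2\,\mathrm{KE} = D k_B T$.

Chain masses follow $q_1 = D k_B T \tau^2$, $q_{j>1} = k_B T \tau^2$.
Each chain contributes
$\sum_j p_{\eta_j}^2/2q_j + D k_B T \eta_1 + k_B T \sum_{j>1} \eta_j$
to the conserved quantity, whose drift is the primary correctness
diagnostic: on the five-water validation fixture the measured drift is
below $10^{-7}$ Hartree atom$^{-1}$ ps$^{-1}$ in both NVE and
three-chain NVT runs (the acceptance script and test suite recompute
this).

## Electrostatic embedding and the quantum-region surrogate

The embedding layer couples MM cores and shells to a *surrogate* charge
density standing in for a quantum subsystem. The surrogate is deliberately
not an electronic-structure method: it exists to exercise every coupling
term and the three-thermostat architecture with exactly conserved forces.
It represents the QM region as one signed Gaussian charge per nucleus
(net charge per site, folding nuclear and electronic contributions
together; the sum equals the region's net charge) plus, optionally, an
induced point dipole per polarizable site with isotropic polarizability
$\alpha$ (Å$^3$).

Charge-density integrals are evaluated in closed form
($\mathrm{erf}$-screened Coulomb for Gaussian densities) rather than by
grid quadrature, multiplied through a short-range-regularized kernel

$$K(r) = \frac{r_c^n - r^n}{r_c^{n+1} - r^{n+1}}$$

(default $n = 4$, per-species $r_c$ from covalent radii), which is finite
at contact ($K(0) = 1/r_c$, $K(r_c) = n/((n{+}1) r_c)$) and tends to $1/r$.
The kernel is evaluated in a factored polynomial form with no removable
singularity, and its first two derivatives are analytic, so every embedding
force — on MM cores, MM shells, QM nuclei and the dipole variables — is an
exact gradient (verified against central finite differences at
$10^{-6}$ eV/Å).

The dipoles run in either *SCF mode* (relaxed to the self-consistent fixed
point $\mu = -\alpha\,\nabla\phi$ at every evaluation, tolerance
$10^{-8}$ e·Å) or *dynamical mode*, where they are extended degrees of
freedom with fictitious mass, the direct analogue of propagating the
quantum subsystem's variables. The default dipole mass is 0.05 amu —
lighter than the shells' 0.2 amu because the dipole stiffness
$C/\alpha \approx 14$ eV/(e Å)$^2$ is much softer than the shell springs,
and the mass is what sets how tightly the dynamical dipoles track the SCF
solution (measured: better than $10^{-3}$ e·Å over 1 ps on the water
fixture).

## Units and numerical choices

Everything runs in eV / Å / e / amu / fs. Because 1 amu Å$^2$/fs$^2$ is
103.64 eV, kinetic-energy and acceleration conversions carry an explicit
factor (see `units_shellmd()`); energies are reported in eV and, for drift
benchmarks, also in Hartree atomic units.

* **Functional forms.** Bonds and angles are GULP-style harmonics
  $\tfrac12 k (x - x_0)^2$; the silica parameter set lists $k$ in eV/Å$^2$
  and eV/rad$^2$. The structural averages this package reproduces (below)
  come out within the reference spreads under the $\tfrac12 k$ convention,
  which is retained.
* **Dispersion.** 12-6 Lennard-Jones with Lorentz-Berthelot combination,
  10 Å cutoff (capped at the minimum-image radius for small cells) with
  energy shift.
* **Exclusions.** A core and its own shell never interact electrostatically;
  1-2 and 1-3 topological neighbours are excluded from Coulomb and LJ
  (policy configurable: `none`, `12`, `12-13`; default `12-13`, the common
  molecular-mechanics convention for bonded silica potentials).
* **Ewald.** Periodic electrostatics over all core and shell sites with
  parameters auto-tuned from a dimensionless accuracy target:
  $p = -\ln(\mathrm{acc})$, $\alpha = \sqrt p / r_c$,
  $k_\mathrm{cut} = 2\alpha\sqrt p$, real-space cutoff just inside the
  minimum-image radius. The default accuracy is $10^{-5}$ — one decade
  tighter than the common production default of $10^{-4}$ — chosen as the
  point where the reciprocal-space cost stops being the bottleneck of the
  per-step force evaluation while structural observables are converged;
  oracle comparisons in the tests run at $10^{-7}$–$10^{-8}$ and reproduce
  the rock-salt Madelung constant to $<10^{-3}$. Excluded-pair corrections
  are applied at the minimum image; for cells so small that an excluded
  pair approaches the minimum-image radius the compiler warns, and
  supercells of at least 2×2×2 conventional cells should be used.
* **Shell mass and timestep.** The shell mass is a free fictitious
  parameter; the default 0.2 amu puts the O-shell spring frequency near
  2.2 rad/fs ($\sim$12000 cm$^{-1}$), an order of magnitude above the
  silica phonon band, so the default timestep 0.2 fs resolves it with
  $\omega\,\Delta t \approx 0.44$ and the adiabatic separation holds
  without help: in a 5 ps run with no shell thermostat, $T_s$ stays below
  0.5 K. Drift benchmarks use 0.1 fs. The `adiabaticity_monitor()` is the
  guard when either knob is changed: it reports $T_s$ statistics and the
  maximum shell displacement from the instantaneously minimized positions.
* **Shell minimization.** Polak-Ribière conjugate gradient with Armijo
  backtracking, initial step $1/\max\kappa$, force tolerance
  $10^{-4}$ eV/Å. Shells are always minimized before dynamics starts, in
  both propagation modes (the cold-start prescription).
* **Velocity initialization.** Maxwell-Boltzmann on the centre-of-mass
  coordinates at the target temperature, zero relative velocities, exact
  rescaling to the target, explicit seed. Total momentum is removed at
  initialization for open systems; $N_f = 3N - 3$ for open clusters and
  $3N$ for periodic crystals.

## What the generators emulate

`build_crystal()` places Si/O cores on conventional-cell coordinates of
α-quartz (3 SiO$_2$ per cell) and α-cristobalite (4 SiO$_2$ per cell) taken
from standard crystallographic refinements, replicates them, and detects
the Si-O topology by a 2.0 Å cutoff. `build_water_cluster()` assembles
equilibrium-geometry monomers of the bundled flexible polarizable water
stand-in (SPC/Fw-like intramolecular terms; shell charge $-2.2$ e with
$\kappa = 71.27$ eV/Å$^2$, preserving a SWM4-like
$\alpha_O \approx 0.98$ Å$^3$) at random non-overlapping positions
(minimum O-O separation 2.6 Å), deterministically for a given seed. The
shell charge/stiffness pair is deliberately chosen so the shell mode
($\approx 1.9$ rad/fs at the default shell mass) clears the intramolecular
OH-stretch band ($\approx 1.0$ rad/fs): a flexible water with a soft shell
would place the two in resonance and break the adiabatic separability that
a rigid-geometry polarizable water — the kind of model this fixture stands
in for — cannot lose. The water model is a synthetic stand-in assembled from
standard magnitudes, not a published parameter set: conclusions about real
water transfer only qualitatively. Likewise the Gaussian surrogate shares
the *architecture* of a quantum subsystem (cold fictitious variables,
exact coupling forces) but none of its electronic structure, so passing
drift and tracking tests validates the integrator and coupling algebra,
not chemical accuracy of the embedded region.

The silica benchmark (3×3×3 α-cristobalite, 108 Si + 216 O + 216 shells,
2 ps equilibration + 10 ps production, NVT 300 K / shells at 1 K) is the
problem size at which the full pipeline runs in minutes on one CPU while
the structural averages (mean Si-O bond, O-Si-O and Si-O-Si angles) are
already converged with respect to cell size — a 2×2×2 cell reproduces the
same means within the quoted spreads, and the lattice energy per formula
unit agrees between 2×2×2 and 3×3×3 to $10^{-6}$ eV at matched cutoffs.

## Degenerate inputs and tie-breaks

Collinear angle triples raise an error rather than returning an arbitrary
gradient; coincident non-excluded charge sites are a hard error; a
non-neutral periodic system gets a uniform neutralizing background plus a
warning; a shell-free system refuses a shell thermostat and a shell-free
temperature query errors instead of returning 0 K. Minimum-image
resolution for triclinic cells searches the 27 neighbouring images after a
fractional wrap, which is exact for any cell at least twice as long as the
interaction range along each perpendicular height.

## Known limitations

* No pressure/stress tensor, barostats, constraint algorithms or multiple
  timestepping; NVE/NVT only.
* The embedding layer supports open (non-periodic) QM/MM assemblies; a
  periodic crystal with an embedded region is not implemented.
* Geometry statistics use core positions; the shells are fictitious and do
  not enter structural averages.
* Very small periodic cells (one conventional cell) are rejected only by a
  warning, but their excluded-pair images are physically ambiguous;
  use them for smoke tests, not production numbers.
* Extended-Lagrangian and minimize-each-step propagation are genuinely
  different dynamics: the shell inertia dresses the vibrational modes at
  $O(m_k/M)$, and in anharmonic thermal systems that small difference is
  chaotically amplified to the thermal-displacement scale (a few times
  $10^{-2}$ Å) within about half a picosecond, independent of the shell
  mass. Quantitative trajectory agreement between the two modes is
  therefore meaningful only over a few tenths of a picosecond (or in
  near-harmonic systems); the physically robust statements are the bounded
  deviation, the cold shell temperature, and the small displacement from
  the instantaneously minimized shell positions.
* A deliberately broken adiabaticity setting (shell mass increased 100×)
  raises the shell temperature by over an order of magnitude (sub-kelvin to
  several K over 5 ps) and the monitor flags the growth; but because
  $\kappa$(O) is stiff, even those heavy shells oscillate above the silica
  phonon band, the resonant heating channel stays mostly closed, and $T_s$
  saturates at a few K rather than running away within 5 ps. Adiabaticity
  in this force field is robust well beyond the default mass.
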