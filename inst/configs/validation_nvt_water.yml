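# NVT conserved-quantity benchmark: same fixture as validation_nve_water
# with all three NHC chains active (nuclear 300 K, shell 1 K, surrogate
# internal variables at a kinetic-energy target of 0.0007 Hartree).
system:
  source: water_cluster
  n_molecules: 5
forcefield:
  preset: water
shells:
  mass: 0.2
embedding:
  qm_molecule: 1
  mode: dynamical
integrator:
  timestep: 0.1
  nsteps: 50000
thermostats:
  nuclear: {target: 300, tau: 50, links: 4}
  shell: {target: 1, tau: 10, links: 4}
  surrogate: {target_ke_hartree: 0.0007, tau: 10, links: 4}
initialization:
  temperature: 300
  seed: 1
output:
  scalar_stride: 10
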