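# NVE conservation benchmark: five polarizable water molecules (bundled
# stand-in model), one molecule treated as an embedded quantum region via
# the Gaussian-density surrogate with dynamical internal polarization.
# dt = 0.1 fs, 5 ps; the summary reports the total-energy drift per atom
# per ps in atomic units.
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
initialization:
  temperature: 300
  seed: 1
output:
  scalar_stride: 10
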