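# NVT benchmark: alpha-cristobalite with the p-MZHB polarizable force field.
# 3x3x3 conventional supercell (108 Si + 216 O cores + 216 O shells),
# 2 ps equilibration + 10 ps production at 300 K, dual NHC thermostats
# (nuclear 300 K, shell 1 K). Produces the Si-O / O-Si-O / Si-O-Si
# structural averages.
system:
  source: crystal
  polymorph: alpha_cristobalite
  replication: [3, 3, 3]
forcefield:
  preset: pmzhb
shells:
  attach: true
  mass: 0.2
integrator:
  timestep: 0.2
  shell_mode: extended_lagrangian
  equilibration_steps: 10000
  nsteps: 50000
thermostats:
  nuclear: {target: 300, tau: 50, links: 4}
  shell: {target: 1, tau: 10, links: 4}
initialization:
  temperature: 300
  seed: 1
output:
  scalar_stride: 25
  frame_stride: 200
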