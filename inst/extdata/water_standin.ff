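# shell-model force field
[bonds]
O      H      91.86  1.012
[angles]
H       O       H       6.582   113.24
[lj]
O         0.006737  3.165   
[charges]
O      core    1.38
O      shell  -2.20
H      core    0.41
[springs]
O      71.27
[policies]
exclusion_policy = 12-13
lj_cutoff = 10
lj_shift = TRUE
ewald_accuracy = 1e-05
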