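# shell-model force field
[bonds]
Si    O     23.3  1.62
[angles]
O         Si        O         6.061057  109.4   
Si        O         Si        1.766554  149.8   
[lj]
Si       0.00864  2.20   
O        0.00324  1.77   
[charges]
Si         core        0.700000
O          core        1.387258
O          shell      -1.737258
[springs]
O        99.4732
[policies]
exclusion_policy = 12-13
lj_cutoff = 10
lj_shift = TRUE
ewald_accuracy = 1e-05
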