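# Reference disk chamber: 490 rods of L/D = 15 at packing fraction 0.20.
L_over_D: 15
eta: 0.20
R_outer: 40
R_inner: 0
H: 6
n_sweeps: 200000
sample_every: 200
seed: 1
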