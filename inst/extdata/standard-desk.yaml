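# Desk-scale standard-regime configuration: reduced network and a
# coarser integration step, otherwise the default study conditions
# (6 input groups per stimulus at connection probability 1/3).
n_associative: 200
groups_per_stimulus: 6
input_probability: 0.3333333333333333
regime: standard
master_seed: 1
dt: 0.05
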