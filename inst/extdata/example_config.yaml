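method: luba
sample_rate: 20
v_max: 0.993
t_max: 240
wear_threshold: 0.7
arm_selection: worst_sum
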