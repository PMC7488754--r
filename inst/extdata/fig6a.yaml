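# Recycling scan at the minimum varying-parameter set: periodic at low
# k_rz, stationary at high k_rz, transition near 0.55-0.56.
mode: scan
scan_parameter: k_rz
scan_from: 0
scan_to: 1
scan_step: 0.01
couple_k_dz: true
h_x: 1
h_b: 5
k_x: 10
k_b: 100
K_a: 1
tau_a: 1
tau_b: 2
tau_r: 3
tau_e: 3
section_level: 2
n_starts: 1
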