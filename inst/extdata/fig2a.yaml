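# Translation-delay scan at 25% recycling: tau_e swept over [3, 5] with the
# basic set otherwise, short delays tau_a=1, tau_b=2, tau_r=3, Poincare
# plane x = 2. Reveals the coexisting simple-cycle and irregular branches.
mode: scan
scan_parameter: tau_e
scan_from: 3
scan_to: 5
scan_step: 0.02
k_rz: 0.25
k_dz: 0.75
tau_a: 1
tau_b: 2
tau_r: 3
section_level: 2
n_starts: 12
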