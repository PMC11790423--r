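# Linear viscoelastic shear wave with the three-mechanism gelatin model;
# the quasi-analytic FFT solution is the reference. Loading frequency
# 16*pi*c_inf/L ~ 82.3 rad/s.
problem: viscoelastic_1d
material: gelatin_tripathi
scheme: muscl
L: 1.0
dx: 0.002
epsilon: 0.9
Gamma: 0.95
Omega: 82.33    # rad/s
amplitude: 0.001
final_time: 0.18
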