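# Point-forced 1D shear problem on [-L/2, L/2]: sinusoidal point source at
# X = 0, first-order LLF scheme, non-reflecting boundaries. Omega defaults
# to 9*pi*c_inf/L (~46.3 rad/s for gelatin).
problem: forced_1d
material: gelatin_tripathi
elastic: true
scheme: llf
L: 1.0          # m
dx: 0.002       # m
epsilon: 0.9
Gamma: 0.95
amplitude: 1.0
final_time: 0.18   # s
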