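# Nonlinear elastic run exhibiting compression-shear coupling: point source
# polarised along Y, no relaxation mechanisms. Sweep the amplitude over
# [0.01, 1] to trace the coupling curve.
problem: nonlinear_1d
material: gelatin_tripathi
elastic: true
scheme: muscl
L: 1.0
dx: 0.001
epsilon: 0.8
Gamma: 0.95
Omega: 82.33
amplitude: 1.0
final_time: 0.08
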