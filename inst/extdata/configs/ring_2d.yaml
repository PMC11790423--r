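# Axisymmetric 2D focusing problem: source distributed on a circle of
# radius R, vertical polarisation (v3), telescopic shearing motion.
# Full-resolution mesh; coarsen dx for quick desk-scale runs.
problem: ring_2d
material: gelatin_tripathi
scheme: muscl
L: 0.6          # square side, m
dx: 0.002
R: 0.2          # ring radius, m
epsilon: 0.9
Gamma: 0.95
Omega: 82.33
amplitude: 0.005
final_time: 0.15
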