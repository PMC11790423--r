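# 3D spherical-wave problem: truncated Gaussian source (sigma = 18 mm,
# cutoff 3.25 sigma) polarised along Y at the centre of a 0.6 m cube.
# Full-resolution mesh; coarsen dx for quick desk-scale runs.
problem: sphere_3d
material: gelatin_tripathi
scheme: muscl
L: 0.6
dx: 0.006
sigma: 0.018    # m
epsilon: 0.9
Gamma: 0.95
Omega: 82.33
amplitude: 0.005
final_time: 0.18
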