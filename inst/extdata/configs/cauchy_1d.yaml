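# Smooth right-going Cauchy problem used for convergence-order estimation:
# supplying dx_ladder makes run_experiment() return a convergence report
# fitted against the exact translated pulse over X in ]0.02, 0.47[.
problem: cauchy_1d
material: gelatin_tripathi
elastic: true
scheme: muscl
L: 1.0
dx_ladder: [0.001, 0.0005, 0.00025]   # m, strictly decreasing
epsilon: 0.9
Gamma: 0.95
final_time: 0.18
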