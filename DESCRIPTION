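Package: softshock
Title: Finite-Volume Simulation of Shear Shock Waves in Soft Viscoelastic Solids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates nonlinear wave propagation in incompressible
    quasi-linear viscoelastic (QLV) soft solids such as gelatin and brain
    tissue, using a Lagrangian Godunov-type finite-volume method with
    artificial compressibility. Provides the Mooney-Rivlin/Yeoh QLV
    constitutive law with stress-like memory variables, local Lax-Friedrichs
    (Rusanov) sweeps with dimensional splitting, optional MUSCL-Hancock
    reconstruction with minmod limiting, exact relaxation sub-steps composed
    by Strang splitting, and CFL time-step control. Companion analysis tools
    include the viscoelastic dispersion relation, FFT-synthesised
    quasi-analytic reference solutions, von Neumann amplification factors,
    modified-equation order predictions, acoustic-tensor wave speeds, and a
    config-driven experiment harness with convergence-order estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0), deSolve, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
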