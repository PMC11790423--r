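---
title: "Artificial compressibility for shear waves in soft viscoelastic solids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Artificial compressibility for shear waves in soft viscoelastic solids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(softshock)
```

## The physical problem

Soft tissues such as brain and gelatin are nearly incompressible: their bulk
modulus exceeds the shear modulus by five to six orders of magnitude. Under
dynamic transverse loading they carry *shear* waves at a few metres per
second, and because the shear wave speed increases with strain (the
nonlinearity parameter $\beta > 0$), smooth velocity profiles steepen and
form shear shocks in finite time. Shock formation in the brain has been
proposed as a mechanism for deep traumatic injury, which motivates
simulation tools that combine three ingredients:

1. a finite-strain constitutive model with experimentally calibrated
   viscoelasticity,
2. an incompressibility treatment compatible with explicit shock-capturing
   schemes, and
3. a Godunov-type finite-volume discretisation with slope limiting.

`softshock` implements this combination in Lagrangian form on structured
1D/2D/3D grids.

## Constitutive model

The elastic response derives from the combined Mooney–Rivlin/Yeoh strain
energy
$$\bar W = C_{10}(\bar I_1 - 3) + C_{01}(\bar I_2 - 3) + C_{20}(\bar I_1-3)^2,$$
evaluated on the volume-preserving strain $\bar C = J^{-2/3} C$,
$J = \det F$. Viscoelasticity follows the quasi-linear (Fung/Simo) theory:
$N$ stress-like memory tensors $S^v_\ell$ relax towards
$g_\ell\,\mathrm{Dev}\,\bar S^e$ at rates $\omega_\ell$,

$$\dot S^v_\ell = \omega_\ell\left(g_\ell\,\bar S^{De} - S^v_\ell\right),
\qquad
S = J U'(J)\, C^{-1} + J^{-2/3}\,\mathrm{Dev}\,\bar S^e
  - \sum_{\ell=1}^N S^v_\ell .$$

The deviatoric projection $\mathrm{Dev}\,S = S - \tfrac13 (S:\bar C)\bar
C^{-1}$ is taken with respect to the isochoric strain throughout the
compressible branch, which keeps $\bar S^{De}:\bar C = 0$ exactly and makes
the memory tensors trace-free in the linear regime.

The shipped preset `qlv_gelatin()` is a gelatin sample with
$\rho_0 = 1000$ kg/m³, $\mu = 2.684$ kPa, $\beta = 4.4$ and three
relaxation mechanisms ($g_\ell$ = 0.0434, 0.0466, 0.2213 at
$\omega_\ell/2\pi$ = 10, 100, 1000 Hz). With the usual soft-tissue
assumption $C_{01}=0$ these give $C_{10} = 1.342$ kPa,
$C_{20} = 1.968$ kPa, an instantaneous shear speed
$c_\infty = 1.638$ m/s, an equilibrium speed $c_0 = 1.360$ m/s, and a
phase velocity of 1.42 m/s at 75 Hz:

```{r}
gel <- qlv_gelatin()
dispersion(2 * pi * 75, gel)$phase_velocity
```

`Remark.` The package exposes $C_{01}$, but all presets set it to zero: the
assumption is standard for exponential-type (Demiray–Fung) fits of soft
tissue, although fourth-order elasticity fits would suggest otherwise. Users
fitting their own Rivlin coefficients can pass a nonzero value.

## Artificial compressibility

Exact incompressibility ($J \equiv 1$) demands a global pressure solve at
every step. Instead, the constraint is relaxed into a stiff barotropic law
$$p = -K (J - 1), \qquad K = \mu/\epsilon,$$
with compressibility ratio $\epsilon = \mu/K \ll 1$. Constraint violations
are then carried away by *artificial* compression waves of speed
$$\frac{c_1}{c_\infty} = \sqrt{\tfrac43 + \tfrac1\epsilon} > \sqrt{\tfrac43}
\approx 1.155 \quad\text{for every } \epsilon > 0,$$
so the scheme stays fully explicit. The price is a stiffer CFL restriction
(the global time step scales with $1/c_1$) and an over-dissipation of shear
waves by the Rusanov flux, whose dissipation coefficient is proportional to
the *fastest* speed. The corresponding Poisson ratio is
$\nu = (1-2\epsilon/3)/(2(1+\epsilon/3))$; $\epsilon = 0.02$ gives
$\nu = 0.49$.

Two usage policies are supported:

* constant $\epsilon$ (default 0.9 in the shipped experiments): cheap, but
  the solution converges to the *weakly compressible* model, not the
  incompressible one;
* mesh-dependent $\epsilon = A(\Delta x/L)^\alpha$ with $0 \le \alpha < 2$:
  converges to the incompressible solution at the reduced order
  $1 - \alpha/2$ in shear (see `predicted_order()`), the trade-off
  quantified by the modified-equation analysis.

## Numerical scheme

The equations of motion are written as a first-order system in the
$12 + 6N$ conserved variables $(F, v, S^v_1, \dots, S^v_N)$ per cell.
One time step composes, in Strang fashion:

1. half an *exact* relaxation step
   $S^v_\ell \leftarrow e^{-\omega_\ell \Delta t/2} S^v_\ell +
   (1-e^{-\omega_\ell \Delta t/2}) g_\ell \bar S^{De}$ (unconditionally
   stable, so the stiff relaxation never restricts $\Delta t$);
2. dimensionally split finite-volume sweeps along X, Y, Z with the local
   Lax–Friedrichs (Rusanov) flux, optionally preceded by MUSCL–Hancock
   reconstruction with minmod-limited slopes on the conserved variables;
3. the second half relaxation step; then source injection at $t^{n+1}$.

The dissipation speed at each interface is the local maximum of the two
adjacent cell speeds; the global maximum $\bar c$ (recomputed once per
step from the acoustic tensor) sets
$\Delta t = \Gamma \min(\Delta x,\Delta y,\Delta z)/\bar c$ with
$\Gamma = 0.95$ by default. Boundaries use constant extrapolation into the
ghost layers (non-reflecting outflow); a periodic option exists for
conservation tests. Wave speeds come from the acoustic tensor
$Q_{ik} = N_J (\partial P_{iJ}/\partial F_{kL}) N_L$, evaluated by central
finite differences on $F$ (step $10^{-6}\max(1, \lVert F \rVert)$, which
puts the truncation and round-off error of the speed well below the
$10^{-6}$ relative agreement verified against the linear spectrum) with a
closed-form cubic eigensolver; only the three axis directions are scanned,
matching the dimensional splitting.

Design choices worth recording:

* *Limiting variables.* Slopes are limited componentwise on the conserved
  variables — the simplest choice consistent with the named MUSCL–Hancock
  procedure; characteristic limiting would require the full eigenstructure
  that the method deliberately avoids.
* *Predictor admissibility.* If a reconstructed face state reaches
  $\det F \le 0$, that interface reverts to first-order values rather than
  aborting; the abort is reserved for inadmissible *cell* states.
* *Speed refresh.* Per-cell speeds are refreshed once per Strang step (not
  per sweep) and reused for the interface dissipation of all three sweeps,
  so the dissipation uses one consistent speed estimate per step.
* *2D problems* run as 3D fields with a singleton Z axis; singleton sweeps
  are skipped.
* *Ring source rasterisation.* Cells hit by the ring are found by sampling
  $\lceil 2\pi R/\min(\Delta x, \Delta y)\rceil$ equally spaced angles and
  taking the nearest cell column to each, deduplicated. Each selected
  column receives the full $s(t)\Delta t/(\Delta x \Delta y)$ weight,
  following the injection formula literally (no division by the number of
  ring cells).

## Linearised references

On the linearised antiplane system the split scheme reduces, per
polarisation $I$, to a 2×2 stencil whose update the full solver reproduces
to round-off (this is tested). The package therefore integrates the linear
system directly (`lin1d_run()`) for the accuracy studies, with exact
references: the translated pulse for the Cauchy problem and the d'Alembert
solution for the point-forced problem. The linear analysis module provides
the viscoelastic dispersion relation, the FFT-synthesised quasi-analytic
solution (500 samples per period, at least 10 padded periods, power-of-two
length), the von Neumann amplification factor
$\xi = 1-\Gamma+\Gamma\cos\kappa\Delta x \pm
i\,\Gamma (c_I/\bar c)\sin\kappa\Delta x$, and the modified-equation
order prediction $1-\alpha/2$.

One modelling detail: in the compression branch of the dispersion relation
the artificial stiffness $1/\epsilon$ enters *outside* the relaxation
factor — the artificial bulk energy carries no viscoelasticity — which is
also what makes the compression dissipation factor vanish as
$\epsilon \to 0$.

## Study configurations and problem sizes

All studies use the gelatin preset, $\Gamma = 0.95$, domain length 1 m and
error window $]0.02, 0.47[$ unless noted.

* **Order studies** (Cauchy problem, elastic shear branch, $t = 0.18$ s,
  $\Omega = 9\pi c_\infty/L \approx 46.3$ rad/s). The fitted orders are
  0.91 (LLF, $\epsilon = 0.9$), 1.66 (MUSCL, $\epsilon = 0.9$), 0.73
  (LLF, $\epsilon = 4(\Delta x/L)^{0.3}$) and 1.52 (MUSCL, mesh-dependent),
  against theoretical/reported values 0.96/1.67/0.78/1.53. The fits use the
  mesh ladder $\{1, 0.5, 0.25\}$ mm. The choice is deliberate: at
  $t = 0.18$ s the 8 mm error is comparable to the signal norm itself (the
  von Neumann factor removes the second harmonic within ~60 steps), so
  coarser ladders measure error saturation, not the convergence rate.
  Pairwise orders stabilise from 0.5 mm downwards, which defines the
  asymptotic regime used for the fit.
* **Locking study** (forced problem, both polarisations, relative error in
  the kinematic energy norm $\sqrt{v_1^2+v_2^2}$, $\epsilon \in \{0.02,
  0.1, 0.5\}$, ladder $\{0.25, 0.125, 0.0625\}$ mm). Fitted orders 0.89,
  0.95, 0.98: the spread of 0.09 shows the discretisation is locking-free —
  smaller $\epsilon$ raises the error constant (the effective shear Courant
  number $\Gamma c_\infty/\bar c$ drops) but not the rate. The finer ladder
  is needed for the same saturation reason as above, now amplified at
  small $\epsilon$.
* **Coupling study** (nonlinear elastic, $\epsilon = 0.8$,
  $\Delta x = 1$ mm, $\Omega \approx 82.3$ rad/s, $t = 0.08$ s, amplitudes
  0.25–1). A shear strain $\gamma$ drags along a compression strain
  $\partial_X u_1 \approx \tfrac13\epsilon\gamma^2(1+\tfrac23\beta\gamma^2)$
  at leading order in $\epsilon$. The measured-to-predicted ratio is
  constant across the amplitude sweep to within 15%, with an absolute
  offset of ~20% at $\epsilon = 0.8$. That offset is a genuine
  higher-order-in-$\epsilon$ effect, not a solver error: solving the exact
  travelling-wave balance $\rho_0 c^2 a = P_{11}(a, \gamma)$ with the
  package's own stress gives ratios 0.78 at $\epsilon = 0.8$, 0.97 at
  $\epsilon = 0.1$ and 0.995 at $\epsilon = 0.01$, converging to the
  leading-order formula.
* **2D/3D demonstrations** run scaled down (ring: 0.6 m square at
  $\Delta x = 12$ mm; sphere: 0.3 m cube at 15 mm) and are asserted
  qualitatively only: inward focusing of the ring-driven wave, approximate
  axisymmetry on the square grid, near-superposition of nonlinear and
  linearised spherical shear profiles, and the early exit of the artificial
  compression pulse. Full-resolution configurations (2 and 6 mm) ship as YAML
  presets for users with more patience.

## What the synthetic problems do and do not show

Every quantitative check in the package runs on synthetic configurations of
the gelatin model: analytic pulses, manufactured strains, and the
deterministic experiment presets. Passing them shows that the constitutive
law, its linearisation, the wave-speed machinery and the integrator are
mutually consistent and reproduce the analytic limits at the stated rates.
It does not validate the gelatin parameters against new laboratory data,
does not exercise heterogeneous or anatomically realistic geometries
(uniform material, block domains only), and does not probe regimes beyond
moderate strain where the Mooney–Rivlin/Yeoh truncation itself expires.

## Numerical and degenerate-input policy

* Inadmissible cell states ($\det F \le 0$) abort with the first offending
  cell index; unimodularity checks use $|{\det - 1}| < 10^{-10}$.
* Acoustic-tensor spectra: a complex pair beyond a relative discriminant
  tolerance of $10^{-12}$, or an eigenvalue below
  $-10^{-8}\rho_0 c_\infty^2$, raises a loss-of-hyperbolicity error; tiny
  negative eigenvalues are clipped to zero.
* $N = 0$ mechanisms degenerates to pure elasticity; the relaxation
  operator is then the identity and the Strang composition reduces to the
  hyperbolic step.
* The FFT synthesiser refuses evaluations whose propagation delay exceeds
  the padded record length instead of aliasing silently.
* Ties in nearest-cell selections (sources, receivers) resolve to the
  lower index via `which.min`.

## Known limitations

* First-order dimensional splitting bounds the multi-dimensional accuracy
  even with MUSCL reconstruction, and the Rusanov flux ties shear-wave
  dissipation to the artificial compression speed — the central accuracy
  cost of the method.
* No absorbing layers or traction/clamped boundaries: outflow extrapolation
  only.
* The R implementation vectorises over cells; full-resolution 3D runs
  (~10⁶ cells) are feasible but slow — expect minutes per thousand steps,
  and prefer the shipped coarsened presets for exploration.
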