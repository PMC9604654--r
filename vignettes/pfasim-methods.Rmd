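---
title: "Simulating pulsed-field ablation in fibrous myocardium: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating pulsed-field ablation in fibrous myocardium: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfasim)
```

## The problem

Pulsed-field ablation (PFA) destroys myocardium by irreversible
electroporation (IRE): microsecond high-voltage pulses permeabilize cell
membranes wherever the local electric field magnitude exceeds a lethal
threshold, conventionally 1000 V/cm (1e5 V/m) for cardiac cells. Because
the lesion is defined by the field distribution, anything that shapes that
distribution shapes the lesion. Atrial myocardium is fibrous: electrical
conductivity along the myocyte bundles (longitudinal, $\sigma_l$) exceeds
conductivity across them (transverse, $\sigma_t$) by a ratio $R$ between
about 1.4 (healthy tissue) and 6 or more (fibrillating, fibrotic tissue).
`pfasim` simulates a two-electrode ablation catheter in contact with a
myocardial wall and quantifies how this anisotropic conductivity (AC),
compared against the isotropic simplification (IC), changes the computed
lesion — its endocardial surface area, its volume, and the per-axis extents
of the threshold isosurface — and the accompanying temperature rise.

## Governing model

The pulse is quasi-static: on microsecond time scales capacitive currents
are negligible, so each pulse sees the stationary conduction problem

$$\nabla \cdot (\sigma(\mathbf{x}, |\mathbf{E}|)\, \nabla V) = 0, \qquad
  \mathbf{E} = -\nabla V, \qquad \mathbf{J} = \sigma \mathbf{E},$$

with the pulse amplitude applied as a Dirichlet value on the driven
electrode, ground on the return electrode, and zero normal flux on the
remaining boundaries (epicardium, catheter shaft insulation, outer box).
Joule heating is $Q = \mathbf{E}^\top \sigma \mathbf{E}$, which reduces to
$\sigma |\mathbf{E}|^2$ for scalar conductivity.

**Anisotropy.** Per myocardial element with unit fiber direction
$\mathbf{A} = (\alpha, \beta, \gamma)$,

$$\sigma_a = \sigma_t I + (\sigma_l - \sigma_t)\, \mathbf{A}\mathbf{A}^\top,$$

a symmetric positive-definite tensor with eigenvalues
$\{\sigma_l, \sigma_t, \sigma_t\}$. The anisotropic pair is tied to the
isotropic baseline $\sigma_i$ by the mean-and-ratio split
$\sigma_l/\sigma_t = R$, $(\sigma_l + \sigma_t)/2 = \sigma_i$, i.e.
$\sigma_l = 2R\sigma_i/(R+1)$ and $\sigma_t = 2\sigma_i/(R+1)$. The four
built-in groups (`conductivity_groups()`) use $R \in \{1.429, 3.75, 4.98,
6.25\}$ with $\sigma_i = 0.0537$ S/m; the two smaller ratios represent
normal myocardium, the two larger ones fibrotic myocardium in atrial
fibrillation.

**Electroporation.** Membrane poration raises tissue conductivity with the
local field. The model is the standard sigmoid

$$\sigma(E) = \sigma_\mathrm{lo} + \frac{\sigma_1 - \sigma_\mathrm{lo}}
  {1 + 10\, e^{-(|E| - 58000)/3000}},$$

with $|E|$ in V/m, the pre-electroporation baseline
$\sigma_\mathrm{lo}$, and the post-electroporation plateau
$\sigma_1 = 0.281$ S/m. In IC mode the baseline is $\sigma_i = 0.0537$ S/m.
In AC mode the sigmoid is applied *independently* to $\sigma_l$ and
$\sigma_t$, so both principal values rise from their distinct baselines to
the same plateau: fully electroporated tissue loses its anisotropy. The
alternative — scaling the whole tensor so that $R$ is preserved after
electroporation — was rejected because poration physically short-circuits
the membrane resistance in every direction. The model is memoryless
(conductivity follows the instantaneous field, with no pore-density state
between pulses), which is why a single stationary solve per amplitude
suffices: the biphasic polarity reversal leaves $|\mathbf{E}|$ and $Q$
unchanged.

**Heat.** Temperature follows the Pennes bioheat equation with the
perfusion and metabolic terms omitted (both are orders of magnitude below
the pulsed Joule source on a 1 s protocol) and the blood-motion loss
retained:

$$\rho c\, \frac{\partial T}{\partial t} =
  \nabla \cdot (k \nabla T) + Q\, g(t) - \rho c\, \mathbf{u} \cdot \nabla T,$$

where $g(t) \in \{0, 1\}$ is the pulse gating signal. Intracardiac flow is
*prescribed*, not solved: a plug or channel (Poiseuille-type) profile over
the blood region stands in for the pulsatile chamber flow, whose
computation would require a full CFD solve that is deliberately out of
scope. The Reynolds helper (`reynolds_number()`) checks that prescribed
speeds remain in the laminar regime the model assumes.

## Synthetic tissue scenarios

Patient-specific atrial geometry is not available to this package, and
reconstructing one from imaging is out of scope. The effects of interest —
field-shaped lesion anisotropy local to a contact catheter — are local, so
the scenarios are desk-scale patches:

* **Slab** (`build_slab_scenario()`): a square myocardial wall of uniform
  thickness 2.4 mm (the mean human left-atrial wall thickness) under a
  blood pool, with a straight 7 F catheter (1 F = 1/3 mm) lying parallel
  to the endocardium: two 2 mm electrodes separated by a 2.5 mm insulated
  shaft, pressed 0.5 mm into the wall to emulate contact pressure. The
  catheter is a capsule (cylinder with hemispherical caps) subtracted from
  the wall by voxel tagging.
* **Ostium** (`build_ostium_scenario()`): the slab with a circular
  transmural hole emulating a pulmonary-vein ostium, the catheter locally
  parallel to the rim — the geometry of circumferential vein isolation.

Fiber architecture is parametric (`make_fiber_field()`): `UNIFORM` (a
parallel bundle at a set angle to the catheter, the roof-line situation),
`CIRCUMFERENTIAL` (tangents around a center, the peri-ostial situation),
and `CROSSING_BUNDLES` (two oblique bundles blended across a dividing
line, the posterior-wall situation). All fibers are in-plane unit vectors
stored per element; transmural fiber rotation is not modeled.

What these scenarios do *not* emulate: wall curvature and thickness
variation, trabeculation, the true rule-based atrial fiber map, and
pulsatile flow. Results on them validate the numerics and the *mechanisms*;
they are not patient predictions.

## Discretization and numerics

* **Grid.** Structured axis-aligned hexahedra (default target spacing
  400 µm, the resolution regime established for convergence of this
  problem class; the builders accept coarser grids for reduced runs with a
  warning). Regions (myocardium, blood, electrode metal, insulator) are
  assigned by cell centroid. Trilinear elements; per-element fields from
  the centroid gradient.
* **Assembly.** The element stiffness is a conductivity-weighted sum of six
  precomputed 8×8 component matrices (one per packed tensor component),
  assembled sparsely via `Matrix`. Electrode metal (4.6e6 S/m, seven
  orders above tissue) is treated as an equipotential: its nodes are
  Dirichlet-constrained and its cells excluded, which sidesteps an
  ill-conditioned contrast without measurable error.
* **Picard iteration.** The $\sigma(E)$ nonlinearity is solved by fixed
  point: solve, update element fields, update conductivity with
  under-relaxation (default 0.7), repeat until the scaled change in $V$
  falls below 1e-6. The sigmoid is steep (3 kV/m slope against a 58 kV/m
  center), and a fixed relaxation factor can limit-cycle — elements near
  the transition flip between branches. The loop therefore halves the
  relaxation whenever the residual stalls; on the reference slab this
  converges in roughly 30–40 iterations. The sparse Cholesky symbolic
  analysis is reused across iterations. Non-convergence raises an error,
  never returns silently.
* **Electrode current.** Computed as the stiffness-matrix reaction sum over
  the electrode's constrained nodes — the consistent-flux form of the
  surface integral of $\mathbf{J}\cdot\mathbf{n}$. It is conservative by
  construction: left and right currents cancel to solver precision.
* **Thermal stepping.** Implicit (backward) Euler with lumped mass;
  first-order upwind for the advective term on the node lattice, with
  inflow nodes held at 37 °C; both are unconditionally stable, so the
  stiff on/off source needs no step restriction beyond accuracy. `GATED`
  mode steps the exact pulse schedule (default 25 µs inside trains, about
  2 ms between trains; each segment's step divides its duration exactly);
  `DUTY_AVERAGED` spreads the source by the protocol duty factor
  (on-time/total = 0.4 %). One sparse LU per distinct step size is cached.
  Temperatures are in °C throughout; offsets cancel in every retained term.
* **Lesion metrics.** Element $|\mathbf{E}|$ is adjacency-averaged to nodes
  within the myocardium; each hexahedron splits into the six equal-volume
  Kuhn tetrahedra, on which the linear interpolant gives closed-form
  supra-threshold partial volumes (a divided-difference formula, exact for
  linear fields), marching-tetrahedra isosurface triangles, and
  closed-form triangle area fractions on the endocardial faces. Exact ties
  at the threshold are broken by a deterministic 1e-9 relative jitter; the
  threshold itself is a strict inequality (field *exceeding* 1000 V/cm).
  Extents are max−min of the isosurface vertex coordinates along the
  scenario axes (x along the catheter, z the wall normal).

## The pulse protocol

Defaults reproduce the reference generator settings: 5 trains × 8 biphasic
pulses, 100 µs pulse width, 100 µs intra-train interval, 198.4 ms
train-to-train pause — exactly 1 s of protocol containing 4 ms of on-time.
The train is read as 8 × (pulse + interval) followed by the train pause;
this is the only reading consistent with the printed 1 s total
(5 × 1.6 ms + 5 × 198.4 ms). Polarity alternation is tracked per pulse for
waveform export but cannot affect $|\mathbf{E}|$, $Q$, or temperature.

## What the electroporation sigmoid does to the AC-vs-IC comparison

A finding this package's tests document explicitly: with the sigmoid
engaged in both modes, the lesion threshold (1e5 V/m) lies far above the
sigmoid center (5.8e4 V/m), so *every point on the lesion boundary sits in
fully electroporated tissue* whose conductivity has already converged to
the isotropic plateau $\sigma_1$ in both AC and IC modes. On the slab
scenarios the AC and IC lesion metrics then agree to within a fraction of
a percent, and the ordering of small residual differences varies with
amplitude and domain size. The pure fiber-anisotropy effect on the lesion
— elongation along the bundle direction and AC/IC volume separation —
appears when the comparison is made at the baseline
(pre-electroporation) conductivities, which `run_config(field_dependent =
FALSE)` and the solver's `field_dependent` switch expose; the package's
acceptance suite measures the comparison under the full field-dependent
model and reports what it finds. A related consequence of the plateau,
which the tests do confirm, is that the four anisotropy groups produce
nearly identical isosurfaces once the sigmoid saturates (extent spread
well under 1 mm).

## Numerical verification

The solver and metrics are checked against closed-form oracles rather than
against other codes:

* parallel plates: exact 1-D field, Ohmic current, and discrete current
  conservation (trilinear elements reproduce linear potentials exactly);
* a monopole source shell: the potential of a point source imposed on a
  shell of nodes propagates through the discrete Laplacian to sub-percent
  accuracy over 1.5–5 source radii;
* anisotropy via coordinate stretching: a diagonal-tensor solve equals the
  isotropic solve on a $\,x_k/\sqrt{\sigma_k}$-stretched grid to machine
  precision (the two stiffness matrices are exactly proportional);
* adiabatic heating: $\Delta T = Q\, t_\mathrm{on} / (\rho c)$ exactly for
  a uniform insulated block, and $T \equiv 37$ °C without a source;
* partial volumes and area fractions against Monte-Carlo integration on
  random tetrahedra/triangles; isosurfaces of linear ramps and
  point-source fields against planes and spheres.

One artifact deserves note: the voxelized catheter produces staircase
corners at the electrode–tissue contact where the discrete field (and the
resulting Joule peak) is inflated relative to a smooth capsule — at 0.8 mm
spacing the hottest corner node reaches about 68 °C under the default
1000 V protocol, while the 99th percentile of myocardial temperature stays
near 45 °C and the gated and duty-averaged fields agree to 0.01 °C on
average. Thermal assertions are therefore made on bulk quantities, not the
single corner node.

## Problem sizes

The shipped tests run on reduced geometries chosen once for this package:
a 26.4 mm square patch at 0.8 mm spacing (about 10k cells) for scenario
solves, 30–40 cell boxes for the analytic oracles, and the full
experiment grid (four groups × two modes × three amplitudes) at the same
reduced slab. The scenario defaults themselves (28 mm patch, 400 µm
spacing) are what a workstation study would use.

## Known limitations

* No patient geometry: flat/annular patches only; curvature effects and
  patient-frame extent axes are out of reach.
* Memoryless electroporation: no pore-density dynamics, no
  irreversibility hysteresis between pulses — a point below threshold in
  the converged field is counted unablated even if a transient exceeded it.
* Prescribed blood flow, no CFD; no-slip is only approximated by the
  interface averaging of the upwind scheme.
* No thermal damage integral (the protocol is non-thermal by design);
  no temperature-dependent material properties.
* Voxelized contact: corner field singularities are sharper than a
  conforming mesh would give; peak-node temperatures should be read as
  upper bounds.
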