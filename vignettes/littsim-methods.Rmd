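---
title: "littsim: model, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{littsim: model, numerics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

littsim simulates interstitial focal laser ablation (laser interstitial
thermal therapy) of a homogeneous soft-tissue block around a cylindrical
diffusing fiber, and quantifies the resulting thermal lesion. This vignette
is the package's own account of the science it implements: the governing
model and its assumptions, the parameters that matter, the numerical
choices, what the synthetic test fixtures do and do not show, and the known
limitations — including a quantified discrepancy between the reconstructed
laser source term and the published benchmark volumes the package ships for
comparison.

## The bioheat model

Heat transport in perfused tissue is modelled by the Pennes bioheat
equation,

$$\rho C \frac{\partial T}{\partial t}
  = k \nabla^2 T
  + w_{vol}\,\rho_b C_b\,(T_b - T)
  + Q_{abs} + Q_{met},$$

with a single homogeneous tissue compartment. The package works throughout
in a millimetre–gram–second–joule–kelvin unit system, chosen so that every
default constant below can be used verbatim without conversion. All
user-facing temperatures (constructors, configuration files, reports) are
in degrees Celsius and converted exactly once at the interface; internally
fields are kelvin.

Default tissue constants (rat prostate adenocarcinoma at 980 nm, set in
`tissue_properties()`):

| quantity | symbol | default | unit |
|---|---|---|---|
| density | $\rho$ | 0.999e-3 | g/mm³ |
| specific heat | $C$ | 4.20 | J/g/K |
| conductivity | $k$ | 5.52e-4 | W/mm/K |
| blood flow rate | $w_b$ | 0.10 | ml/g/min |
| blood temperature | $T_b$ | 37 | °C |
| metabolic heat | $Q_{met}$ | 0 | W/mm³ |

The derived thermal diffusivity is $\alpha = k/(\rho C) \approx 0.1316$
mm²/s. The perfusion sink uses the volumetric rate
$w_{vol} = w_b\,\rho \cdot 1000/60 \approx 1.665\times10^{-3}$ s⁻¹
(`volumetric_perfusion_rate()`); blood density and specific heat default to
the tissue values, as no separate blood constants are part of the reference
parameter set. Metabolic heating is negligible on the 75 s ablation time
scale and defaults to zero. Tissue properties are constant in temperature:
coagulation-induced changes of conductivity or perfusion shutdown are out
of scope (see Limitations).

### The fiber source: three modes, one open reconstruction

The applicator is a cylindrical diffusing fiber (10 mm diffuser, 0.5 mm
core) delivering a nominal 5 W at 980 nm for 75 s. How that optical power
converts into a *spatial* heat deposition $Q_{abs}$ cannot be uniquely
reconstructed from the measurements available for the reference protocol —
total power, duration, and a single peak temperature of 91 ± 1 °C at the
fiber tip. Light-transport (Monte-Carlo) modelling is deliberately out of
scope. The package therefore implements three interchangeable forcings in
`fiber_source()`:

* **`uniform_capsule`** (reference mode, the default): the total power is
  deposited uniformly in a capsule of radius 4.4 mm around the diffuser
  segment. The radius makes the capsule volume ≈ 1000 mm³, so 5 W
  corresponds to ≈ 5×10⁻³ W/mm³. A nominal volumetric deposition of this
  magnitude is the only reading of the reference setup that is
  dimensionally consistent with a 5 W source: a deposition of 5 W/mm³
  over any region larger than a cubic millimetre would imply kilowatts of
  absorbed power and adiabatic heating of order 10⁵ K over 75 s.
* **`dirichlet_wall`**: no volumetric deposition; the grid nodes inside
  the fiber cylinder are clamped at the measured wall temperature
  (default 91 °C). This brackets the problem from the other side: it
  reproduces the measured peak exactly and deposits only the heat that
  conduction draws through the fiber wall.
* **`radial_exponential`**: deposition
  $\propto e^{-\mu_{eff} d}/\max(d, r_{core})$ with $d$ the distance to
  the diffuser axis, renormalised to the total power — a one-parameter
  stand-in for radially attenuated light, and (for large $\mu_{eff}$) the
  line-source limit used by the verification oracle.

In every volumetric mode the discrete node powers are renormalised against
the finite-volume node weights so the deposited total equals the nominal
power exactly, not merely to quadrature accuracy.

### Boundary and initial conditions

All six outer faces of the block are zero-flux (homogeneous Neumann). The
domain is large compared with the 75 s diffusion length
($\sqrt{4\alpha t} \approx 6$ mm), so the outer boundary condition is
immaterial to the lesion; zero-flux additionally makes adiabatic runs
exactly energy-conserving, which the test suite exploits. A fixed
(Dirichlet) temperature appears only at the fiber wall in `dirichlet_wall`
mode. The initial field is uniform at 37 °C. By default the run ends with
the heating (`cooldown_duration_s = 0`) because lesion metrics are defined
at the end of irradiation; post-irradiation spread can be simulated by
setting a cooldown, during which the source is off and clamps released.

### Fiber placement

The reference protocol places the fiber from an image-derived trajectory
that is not part of the package, so the default placement is the package's
own convention: the diffuser segment is centred in the domain and aligned
with the x axis (the longest axis of the default 70 × 70 × 20 mm block).
Both origin and direction are explicit fields of `fiber_source()`, and
`build_grid()` rejects any placement whose diffuser segment is not
strictly inside the domain.

## Numerics

**Grid.** Regular node-centred lattice: a block of extent $E$ at spacing
$h$ carries $E/h + 1$ nodes per axis (the spacing must divide the extent
evenly), 0-based physical coordinates from the domain corner. Each node
carries a finite-volume weight $h^3$, halved per domain face it lies on;
the weights tile the domain exactly and are used for every volume and
energy integral.

**Space.** 7-point Laplacian; face nodes use the mirrored-ghost form,
which is algebraically identical to the finite-volume discretisation with
half cells at the boundary. Consequences: second-order accuracy in $h$,
and exact discrete energy conservation in adiabatic runs (verified to
float precision in the tests).

**Time.** Backward Euler at $\Delta t = 0.5$ s by default —
unconditionally stable, first-order, and monotone (the no-source scheme
satisfies a discrete maximum principle, also under test).
Crank–Nicolson is available behind `time_integration = "crank_nicolson"`
for smooth problems; it is not the default because its oscillatory modes
interact badly with the discontinuous capsule source at practical step
sizes.

**Linear solver.** Each implicit step solves one sparse system with the
time-independent matrix $(\rho C/\Delta t)I + \theta L$. Grids up to
25 000 nodes (`linear_solver = "auto"`) use a cached sparse LU
factorisation. Larger grids use restarted GMRES (restart 30) with Jacobi
preconditioning, warm-started from the previous step; convergence is
declared when the preconditioned residual falls below
`linear_solver_tolerance` (default 10⁻³) relative to the initial residual.
The matrix is strongly diagonally dominant at the default $\Delta t$
(condition number ≈ 4), so typical steps converge in one or two
iterations; the per-step iteration count and residual are logged. A
non-convergent solve raises an error carrying the residual rather than
returning silently degraded fields. Verification runs in the test suite
tighten the tolerance to isolate discretisation error from solver error.

**Damage accumulation.** The Arrhenius integral
$\Omega = A_f \int_0^\tau e^{-E_a/(R T(t))}\,dt$ is evaluated with the
trapezoidal rule over the simulation's time points, streamed during the
run so large-grid histories need not be stored; `accumulate_damage()`
applies the identical rule to stored histories (the two paths agree to the
last bit in tests) and to single-point time–temperature tables. On a
constant-temperature history the trapezoidal rule is exact, which the
closed-form tests exploit. The integral is additive over concatenated
histories and monotone under pointwise hotter histories.

## Damage kinetics and their internal consistency

Defaults in `kinetic_parameters()`: $A_f = 3.8\times10^{14}$ s⁻¹,
$E_a = 1.084\times10^5$ J/mol. The gas constant defaults to the CODATA
value 8.314462618 J/mol/K but is an explicit parameter, because parameter
tables in the application literature occasionally print non-standard
values for it; pinning $R$ inside the formula would make such tables
impossible to reproduce deliberately.

Two facts about these constants, both asserted in the acceptance tests:

* The constant-temperature threshold reaching $\Omega = 1$ in 75 s is
  $T^* = E_a/(R \ln(A_f \tau)) = 344.1\ \mathrm{K} \approx 71.0\ °C$
  (`threshold_temperature()`, cross-checked against numeric inversion to
  0.01 K). This is far from the 50 ± 1 °C damage-threshold temperature
  commonly quoted for prostate ablation at this exposure: the published
  kinetic constants and the 50 °C claim cannot both hold.
* `calibrate_frequency_factor()` inverts the relation: putting the 75 s
  threshold at 50.0 °C requires $A_f \approx 4.44\times10^{15}$ s⁻¹.
  The package implements both parameterisations and flags the
  inconsistency rather than silently choosing.

The destroyed-concentration fraction is $1 - e^{-\Omega}$; $\Omega = 1$
corresponds to 63.2 % destruction. A reading of $\Omega = 1$ as "100 %
damage" sometimes seen in the application literature is mathematically
untenable for a first-order process and is not adopted. CEM43 uses the
standard 43 °C breakpoint with factors 0.25 below and 0.5 above (the
classic values; they are parameters, not constants, in `cem43()`), with
each interval classified by its mean temperature — exact for the constant
holds used in tests.

## Lesion volumetrics

`isolevel_volume()` measures the super-level set $\{T \ge L\}$ (ties
inside) and reports cc. Two estimators:

* *raw*: sum of finite-volume node weights over qualifying nodes;
* *corrected* (default): cell-based — cells entirely above the level
  contribute $h^3$, interface cells are subsampled on a 4×4×4 midpoint
  lattice with trilinear interpolation and contribute their fractional
  occupancy.

Both are monotone non-increasing in the level. The corrected estimator is
exact for linear fields with node-aligned interfaces and is within 2 % of
the closed form for an 8 mm sphere at 0.5 mm spacing; lattice artifacts
make the raw count oscillate at O($h$) around the truth. For *discontinuous*
fields (e.g. a damage integral that steps from ≈ 8 inside a region to ≈ 0
outside) the trilinear correction smears the jump by design, and the raw
count is the meaningful estimator — the tests compare that way.

`lesion_axes()` reports the bounding extents of the super-level set along
the fiber axis and two perpendicular directions (node span plus one
spacing, so an isolated node has extent $h$), and flags the lesion prolate
when the axial extent strictly dominates — the expected shape around a
linear diffuser. An empty super-level set returns an explicit empty-lesion
row, not an error, so level sweeps do not need exception handling.

## Synthetic fixtures: what passing tests show

`generate_fixture()` builds deterministic synthetic inputs whose
descriptors are closed forms: a spherically symmetric linear temperature
field (iso-volumes are spheres), a Gaussian blob, a uniform field, and a
spatially uniform exponential perfusion-decay history (damage known by
adaptive quadrature). Optional Gaussian node noise is generated from an
explicit seed without touching the caller's RNG stream.

These fixtures verify the *machinery* — volumetrics against geometry,
damage against quadrature, solver against analytic conduction solutions
(perfusion-only exponential decay; the transient line-source
exponential-integral solution, matched within 2 % for r in 1–5 mm at
75 s). They do not emulate real data: no imaging noise or segmentation
uncertainty, no tissue heterogeneity, no perfusion shutdown in coagulated
regions. Passing tests therefore demonstrate that the equations stated
here are solved correctly, not that those equations capture every feature
of an in vivo lesion.

## The validation cohort and the benchmark discrepancy

The package ships two small CSV fixtures: per-subject necrosis volumes for
the ten-rat in vivo validation cohort of the reference protocol (48 h MRI
and histology), and the published benchmark iso-temperature volumes at
43/45/50 °C. `run_pipeline("validate")` reproduces the cohort statistics —
MRI 0.980 ± 0.053 cc, histology 0.974 ± 0.059 cc, Pearson r = 0.877
(sample, n−1, standard deviations; population SDs do not reproduce the
printed values) — and compares a fresh simulation against the benchmark.

The comparison is the package's most important honest result. The
reference reconstruction (uniform-capsule, full nominal 5 W deposited,
0.5 mm grid) yields 3.30 / 2.72 / 1.88 cc at 43 / 45 / 50 °C — correctly
ordered and prolate, with a peak of 94.7 °C next to the measured
91 ± 1 °C, but 1.9–2.4× the benchmark volumes of 1.38 / 1.10 / 0.99 cc.
The gap is not a numerical artifact: 5 W × 75 s = 375 J into tissue with
$\rho C \approx 4.2\times10^{-3}$ J/mm³/K *necessarily* heats roughly
3 cc above the 43 °C level (the adiabatic bound is ≈ 15 cc), whereas the
benchmark volumes are consistent with only ~100–150 J reaching tissue.
The benchmark's own source setup is not recoverable from the published
description (its printed volumetric deposition of "5 W/mm³" is
dimensionally inconsistent with a 5 W source, and its printed fluence
does not match power × time over the stated fiber area); the
`dirichlet_wall` bracket under-shoots the benchmark from the other side
(≈ 0.37 cc at 43 °C). The validation report states this discrepancy
analysis alongside the numbers rather than tuning the deposition geometry
to fit.

## Problem sizes

The package's own test suite runs its verification cases at deliberately
modest sizes: oracle comparisons on grids of 10³–50³ nodes, the
end-to-end reference simulation at 1 mm spacing (≈ 1.1×10⁵ nodes, ~10 s),
and the line-source oracle at 0.5 mm (≈ 3.8×10⁵ nodes, ~1 min). The
acceptance script runs the full 0.5 mm reference grid (≈ 8.2×10⁵ nodes,
~1 min). Volumes computed at 1 mm and 0.5 mm agree to well under 1 %, so
the coarser grid is used wherever turnaround matters.

## Limitations

* Homogeneous tissue; no anatomy, no discrete vessels, no
  temperature-dependent (coagulation-modified) properties, no perfusion
  shutdown, no vaporisation or carbonisation above ~100 °C.
* No light-transport modelling: the three source modes parameterise, not
  derive, the deposition profile — the dominant uncertainty, as the
  benchmark discrepancy quantifies.
* Single first-order Arrhenius process; multi-state damage models and
  functional endpoints beyond Ω and CEM43 are out of scope.
* Regular grids only; no adaptive or unstructured meshing, no image
  registration or segmentation of real lesions.
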