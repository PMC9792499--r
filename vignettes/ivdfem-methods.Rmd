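---
title: "Models and numerics behind ivdfem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerics behind ivdfem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the constitutive models, the wave-speed-based
adaptive time stepping, the synthetic geometry, the solver's numerical
choices, and the calibration machinery — including the choices that were
genuinely open and why they were made the way they were. It states no
empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## Tissue models

The intervertebral disc is modeled as two hyperelastic solids. Both use the
decoupled distortional/dilatational split, with `F̄ = J^{-1/3} F`,
`C̄ = F̄ᵀF̄` (unimodular) and distortional invariants `Ī₁ = tr C̄`,
`Ī₂ = ½[(tr C̄)² − tr C̄²]`.

**Nucleus pulposus (NP)** — gel-like, collagen randomly oriented, hence
isotropic: a compressible Mooney–Rivlin energy
`Ψ = b₁₀(Ī₁−3) + b₀₁(Ī₂−3) + (k/2)(J−1)²`. The shipped preset
(`np_table1`: b₁₀ = 0.12, b₀₁ = 0.03 kPa) pairs with a bulk modulus
k = 29.9 kPa, the value implied by Poisson's ratio 0.495 through the
small-strain identity `k = 2μ₀(1+ν)/(3(1−2ν))` with ground-state shear
modulus `μ₀ = 2(b₁₀+b₀₁)` (`bulk_from_poisson()`). Near-incompressibility is
thus imposed energetically, not by a constraint.

**Annulus fibrosus (AF)** — the same matrix form plus two collagen fiber
families at ±Φ (default 30°) about the local transverse plane, with
structure vectors `M₁, M₂` and distortional fiber invariants
`Ī_{Mi} = M_i·C̄M_i` (squared distortional fiber stretch). Each family
contributes `(a₁/a₂)[exp(a₂⟨Ī_{Mi}−1⟩²) − 1]`; the Macaulay bracket makes
crimped fibers tension-only. Presets: `af_table1` (c₁₀ = 0.18,
c₀₁ = 0.045, a₁ = 2, a₂ = 100, k = 4.35 kPa from ν = 0.45) and `af_table3`
(c₁₀ = 0.016, c₀₁ = 0.001, a₁ = 1, a₂ = 151, k = 170 kPa), a set calibrated
against mean cadaveric range-of-motion curves of non-degenerated segments.

All stresses and tangents are analytic: the second Piola–Kirchhoff stress
via the deviatoric projector applied to the fictitious distortional stress,
and the material elasticity tensor from the closed-form decoupled
expressions, pushed forward to the spatial tensor. The test suite verifies
both against central finite differences of the energy on random states
(1e-6 / 1e-5 relative), plus objectivity, fiber-swap symmetry, tension-only
behavior and the stress-free reference.

**One-sided tangent at fiber lock-on.** At `Ī_M = 1` the fiber stiffness is
one-sided (zero from below, `2a₁` per family from above). The tension branch
is used whenever `Ī_M ≥ 1`: this upper-bounds the wave speed and therefore
errs on the conservative side for the time step.

**Units.** Constructors accept kPa (the unit in which disc moduli are
reported) and store Pa; meshes are in mm; the solver converts to SI
internally. Tissue density is 1000 kg/m³ by default for both tissues —
disc tissue is mostly water, and no specific value is established in the
literature for these models — and is configurable per material.

## Wave speeds and the adaptive time step

For a plane longitudinal wave along unit direction `n` (polarization
`m = n`), `ρ₀v² = J(c_ijkl + σ_ik δ_jl) n_i n_j n_k n_l`. The stable step of
central-difference integration on an element of characteristic length `l_c`
is `Δt = 0.9 l_c / v_max`. Two estimators of `v_max` are implemented:

* **Dense maximization** (`max_wave_speed_theoretical()`): the half-sphere is
  parametrized by spherical angles φ, θ ∈ [0, π); a uniform 181×181 grid is
  scanned and the best grid point polished with Nelder–Mead. The objective is
  smooth and π-periodic, so a grid of that density cannot miss the global
  maximum by more than the polish can recover; the tests verify agreement
  with a brute-force 721×721 grid to 0.1%.
* **Five-direction approximation** (`max_wave_speed_approx()`): the maximum
  over the candidate set {M₁, M₂, M₁+M₂, M₁−M₂, M₁×M₂}, normalized and
  **convected as material lines**: each reference candidate `d` is evaluated
  along the spatial direction `F d / |F d|`. The candidates exploit the AF's
  local orthotropy (the two fiber axes, their bisectors and the lamella
  normal), and convecting them by `F` keeps them on the *current* fiber
  directions — a fiber is a material line, and at large stretch the true
  maximizer migrates toward the stretched fiber axis. The choice of frame
  matters enormously once elements rotate far: probing the raw reference
  directions loses the bound by roughly the element's rigid rotation, and
  rotation-only (corotational or orthonormalized-edge) frames preserve the
  ±30° architecture but miss the stretch-induced migration of the maximizer.
  Material-line convection was adopted as the production path because it is
  the tightest lower bound — i.e., the least conservative admissible time
  step (the acceptance script measures mean ratios of about 1.002 at peak
  load) — and the alternatives remain recoverable by probing `pwave_speed()`
  along any custom direction set. Audits of this family of approximations in
  milder strain regimes report ratios of a few percent with angular
  separations around 10°; there all the frame conventions coincide, and the
  spread described above is a large-deformation effect.

Nucleus elements carry no fiber frame; for an isotropic material the
extremal longitudinal speeds lie along the principal stretch directions, so
`wave_speed_isotropic_max()` takes the maximum over the three spatial
principal directions of `C` — expressed through the eigenvalues of `C`
alone in the solver's vectorized path, which avoids per-element
eigenvector computations.

The solver recomputes every element's `v_max` and the global
`Δt = 0.9·min(l_c/v_max)` at **every step**: that adaptivity is the point of
the five-direction bound, which costs five quadratic forms per element
instead of a 32,761-direction scan. A config switch
(`solver_controls(wavespeed = "theoretical")`) runs the dense path in-run for
audit purposes, at a coarser in-run grid (default 24×24) because the full
grid per element per step is prohibitive. Loss of rank-one convexity along a
probed direction (negative contraction) raises a classed error rather than
returning an imaginary speed: it signals an unstable material state.

In the solver's hot path the directional contraction is evaluated without
forming the elasticity tensor: with `w = Fᵀn` and the rank-one update
`C + t wwᵀ` having linear determinant and invariants in `t`, the full
contraction `c_ijkl n_i n_j n_k n_l` reduces to `4J⁻¹ d²Ψ(C + t wwᵀ)/dt²`,
a handful of scalars per element and direction. The pointwise and batch
paths are verified against each other to machine precision.

## Synthetic spinal-segment geometry

There is no public geometry pipeline to reproduce, so `generate_segment()`
builds a parametric stand-in that covers the same geometric regimes:

* cross-section: a superellipse (default exponent 2.5) with lateral and
  anterior-posterior semi-axes (defaults 25 and 17 mm, lumbar-sized);
* height profile: anterior/posterior heights (defaults 11/9 mm) wedge the
  disc; a skew offset shears the cranial endplate; a gentle outward
  mid-height bulge (3%) shapes the annulus wall;
* degeneration presets: `moderate` (≈30% height loss, mild extra wedge,
  1 mm skew) and `severe` (≈55% height loss, strong wedge, 2.5 mm skew) map
  onto the narrowed, skewed geometries of advanced degeneration;
* nucleus: an inner scaled superellipse holding 40% of the cross-section
  area by default, with a configurable centroid offset (anatomical studies
  place the nucleus near the center, slightly posterior; no established
  numbers exist, so the default is centered).

Meshing maps a structured square grid onto the cross-section with the
concentric (Shirley–Chiu) square-to-disc mapping, smooths the interior
nodes with a few Laplacian sweeps (the mapping's diagonal creases otherwise
seed sliver elements), triangulates each footprint quad along its shorter
diagonal, extrudes through the height profile, and splits each prism into
three tetrahedra with face diagonals chosen through the smallest global
node index — a rule that is automatically conforming between neighbors.
Determinism is structural (no randomness unless node jitter is requested),
so equal specs and seeds give byte-identical meshes. The mesh volume
converges to the analytic spec volume (within 2% at 2 mm nominal size in the
tests; 0.1% at 1.4 mm).

Fiber frames: per AF element, ê₁ is the tangent of the superellipse level
curve through the element centroid (circumferential), ê₂ the local
endplate-to-endplate direction orthonormalized against ê₁, and
`M₁,₂ = cos Φ ê₁ ± sin Φ ê₂`. The characteristic length is the minimum
altitude `l_c = 3V/A_max` — the conservative choice among the common
mesh-deduced lengths, and the one that cannot overestimate the transit
time across the element.

## Explicit quasi-static solver

Total-Lagrangian constant-gradient tetrahedra; internal forces are the exact
gradient of total strain energy with respect to nodal positions (patch test
and rigid-rotation zero-force are asserted in the tests). Row-sum mass
lumping conserves total mass exactly. Time integration is symplectic Euler
(velocity first), equivalent to central difference in this force structure,
with mass-proportional damping applied as an implicit velocity scale
`1/(1 + c·dt)` for unconditional damping stability.

The vertebrae are rigid bodies: the spec interface node layers are tied
kinematically (exact rigid maps, no penalty). The cranial body is free in
all six degrees of freedom and carries the applied torque; the caudal body
may only translate in the moment plane (rotations locked), mirroring
cadaveric test fixtures. Default body mass corresponds to tissue density
over a 5 mm slab footprint. The moment ramps with a C² quintic smoothstep —
two continuous derivatives avoid exciting transients at ramp start/end —
and is then held until kinetic/internal energy < 1%. The energy ledger
(external work vs. internal + kinetic + damped energy) must close within 2%
on every accepted run; runs ending outside the settle window, inverted
elements and kinetic-energy blow-ups raise distinct classed conditions
(`ivdfem_not_converged`, `ivdfem_inversion`, `ivdfem_instability`).

**Ramp time and damping.** The standard cadaveric load protocol (pure
moments to 5 N·m) specifies no loading rate; quasi-static adequacy is
checked, not assumed. The default ramp (0.05 s) is several multiples of the bulk-wave
transit time across the segment, and the shipped tests verify that tripling
the ramp changes the moment-rotation curve only marginally while the
kinetic/internal ratio stays below 1%. Default damping `c = 25/ramp_time`
settles the held state quickly without visibly lagging the ramp.

**Problem sizes.** All shipped computations are desk-scale by design: the
acceptance script runs the anatomical-size segment at 5 mm nominal element
size (≈1200 tetrahedra) and the tests use geometrically scaled discs
(12–14 mm lateral semi-axis) at proportionally scaled moments (≈1 N·m —
moments scale with the cube of the linear dimension at equal tissue
strain; the anatomical 5 N·m inverts elements of a half-size disc). Mesh
dependence is spot-checked by refining the test disc from 5 mm to 3.5 mm
nominal size (< 5% change in peak rotation). Where only the peak (settled)
state matters — wave-speed audits, stability sweeps, refinement checks —
runs use quasi-static mass scaling (a 16x density multiplier, enlarging the
stable step 4x); the kinetic/internal ratio and ledger checks still apply,
and a shipped test verifies that the scaled and unscaled peak rotations
agree to well under a percent. Runs whose
whole moment-rotation curve is consumed (calibration, curve reporting) are
never mass-scaled: the scaled toe visibly lags the ramp.

## Field statistics and the wave-speed audit

`summarize_field()` produces normalized histograms (Freedman–Diaconis bins
by default; pass shared breaks when comparing runs) and exact ECDFs of
per-element pressure (`p = −tr σ/3`, compression positive) and energy
densities. The "ECDF variation" between two runs is implemented as the
Kolmogorov–Smirnov maximum vertical distance, in percent — no other
percentage metric on ECDFs is both symmetric and bounded. The wave-speed
audit computes, per annulus element at peak load, the dense-search speed
and direction against the five-direction values; angular separations use
`arccos |n₁·n₂|` (propagation directions are axes; antipodes identified).

## Inverse-FEM calibration

The objective is the normalized mismatch
`O(p) = (1/n) Σᵢ ((Θᵢᵉˣᵖ − Θᵢˢⁱᵐ(p))/Θₙᵉˣᵖ)²` per load case — the
normalizer is the experimental rotation at the final (largest) moment
increment — averaged with equal weights across cases (no weighting is
established; equal weights are the neutral choice). Simulated rotations are
sampled from the quasi-static ramp at the experimental moment increments,
so one forward run yields a whole curve. Because the objective is a mean of
squared residuals, the minimizer is a bound-constrained Levenberg–Marquardt
iteration on the residual vector with a finite-difference Jacobian, in
log-parameter space: the fiber exponent spans orders of magnitude between
literature and calibrated sets (100 vs 151) with stiff exponential
sensitivity, and log-space makes relative bounds ([0.5×, 2×] of the initial
guess by default) and relative steps natural. Forward-run failures at trial
points return penalized residuals and are logged, not fatal.

**Identifiability of the recovery study.** The shipped `af_table3` preset
was fitted against mean cadaveric range-of-motion curves that are not
publicly deposited, so the calibration machinery is validated by parameter
recovery on synthetic noiseless curves instead. The truth set for recovery
is deliberately *not* the literature preset: with
c₁₀ = 0.18 kPa and a₂ = 100 the simulated segment rotates almost freely
until the fibers lock exponentially, and a ±30% change in c₁₀ then moves
the moment-rotation curve by under 0.05% — the matrix constant is
structurally unidentifiable from ROM data in that regime, for any
optimizer. The recovery study therefore uses a stiffer-matrix,
gentler-fiber annulus (c₁₀ = 20, c₀₁ = 1, a₁ = 2, a₂ = 30 kPa, bulk
modulus from ν = 0.45), where all three free parameters visibly shape the
curve, on the desk-scale disc at 1 N·m with six moment increments. The
tests recover c₁₀, a₁, a₂ within 5% from a ±30% perturbed start.

## What the synthetic data do and do not show

The generator emulates the geometric regimes (wedging, narrowing, skew,
nucleus fraction) and the fiber architecture of lumbar discs, not any
patient's anatomy: endplates are planar, the cross-section is a
superellipse rather than a kidney shape, vertebra geometry is reduced to
rigid bodies at the interfaces, and there are no ligaments or facet
joints. Passing tests therefore demonstrate correctness of the mechanics
and numerics (energies, tangents, wave speeds, time stepping, constraint
handling, calibration machinery) — not anatomical fidelity of predicted
ranges of motion, which with the soft literature parameters and a
disc-only load path are much larger than in vivo values. Peak rotations
are geometry-specific throughout and are not comparison targets.

## Known limitations

* Hyperelastic only: no poro-/viscoelasticity, damage, osmotic swelling or
  fiber dispersion; degeneration enters only through geometry presets.
* Linear displacement tetrahedra in pure displacement form are known to be
  overly stiff near the incompressible limit (volumetric locking); the
  shipped bulk moduli keep ν ≤ 0.495.
* Only longitudinal (m = n) wave speeds are computed; quasi-transverse
  branches of the acoustic tensor would require an eigenvalue solve per
  direction and are not needed for the P-wave time-step bound.
* The five-direction bound is a lower bound on `v_max`; the 0.9 safety
  factor absorbs the few-percent underestimate observed in the audits.
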