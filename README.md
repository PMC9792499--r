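# ivdfem

Explicit finite-element simulation of intervertebral disc (IVD) mechanics on
linear tetrahedral meshes, with an adaptive, deformation-dependent critical
time step derived from acoustic-tensor wave speeds.

## Who this is for

Spine biomechanics groups building finite-element models of spinal segments
face two recurring problems: degenerated discs are narrow, wedged and skewed,
which makes hexahedral meshing fragile, and the anisotropic hyperelastic
tissue models that capture annulus behavior make the stable explicit time
step strongly deformation-dependent, so a constant conservative step wastes
most of the compute. `ivdfem` packages the tetrahedral-element answer to
both: constitutive models for the two disc tissues, a cheap per-element
wave-speed bound that adapts the time step every step, a parametric synthetic
segment generator covering degenerated geometries, a quasi-static explicit
solver for the standard moment load cases, and inverse-FEM calibration of
annulus parameters from range-of-motion curves.

## The model

Both tissues are hyperelastic with a decoupled distortional/dilatational
split. The nucleus pulposus (NP) is a compressible Mooney–Rivlin solid,

&nbsp;&nbsp;Ψ_NP = b₁₀(Ī₁ − 3) + b₀₁(Ī₂ − 3) + (k_NP/2)(J − 1)²,

and the annulus fibrosus (AF) adds two collagen fiber families M₁, M₂ at
±30° about the local transverse plane, with a tension-only exponential
response in the distortional fiber invariants Ī_{Mi} = M_i·C̄M_i:

&nbsp;&nbsp;Ψ_AF = c₁₀(Ī₁ − 3) + c₀₁(Ī₂ − 3) + (k_AF/2)(J − 1)² +
Σᵢ (a₁/a₂)[exp(a₂⟨Ī_{Mi} − 1⟩²) − 1].

Stresses (S = 2∂Ψ/∂C, σ = J⁻¹FSFᵀ) and the material/spatial elasticity
tensors are analytic. For explicit integration, the stable step of each
element is Δt_crit = 0.9·l_c/v_max, where l_c is the minimum tetrahedron
altitude and v_max the fastest longitudinal wave speed,
ρ₀v² = J(c_ijkl + σ_ik δ_jl)n_i n_j n_k n_l. Maximizing v over all unit
directions n is accurate but expensive; the package's production path
instead takes the maximum over five fiber-derived candidate directions
{M₁, M₂, M₁±M₂, M₁×M₂} convected to the current configuration — a lower
bound that tracks the true maximum to within a few percent — and recomputes
the global step every increment. Calibration minimizes the normalized
range-of-motion mismatch O(p) = (1/n)Σᵢ((Θᵢᵉˣᵖ − Θᵢˢⁱᵐ(p))/Θₙᵉˣᵖ)² with a
bound-constrained Levenberg–Marquardt iteration.

## Worked example

```r
library(ivdfem)

np <- material_preset("np_table1")   # b10 = 0.12, b01 = 0.03, k = 29.9 kPa
af <- material_preset("af_table1")   # c10 = 0.18, c01 = 0.045, a1 = 2, a2 = 100, k = 4.35 kPa

mesh <- generate_segment(segment_spec(element_size = 6))
mesh
#> <ivd_mesh> 300 nodes, 972 tets (592 AF / 380 NP), volume 14711.7 mm^3

res <- run_explicit(mesh, np, af, load_case("flexion", moment = 5),
                    solver_controls(ramp_time = 0.05))
res
#> <ivd_result> flexion 5 N*m: ROM 40.913 deg, 25510 steps (dt 1.1e-06..0.000396 s),
#>   KE/Ei 6.1e-08%, ledger closure 0.02%
```

The printout gives the peak range of motion (rotation of the cranial
vertebra about the load axis at the 5 N·m target), the number of explicit
steps with the adaptive time-step range the wave-speed bound produced
(here spanning more than two decades — the reason a constant step is
wasteful), and two quasi-static quality checks: the kinetic/internal energy
ratio and the closure of the external-work/internal-energy ledger.

```r
aud <- wavespeed_audit(res)
aud
#> <ivd_wave_audit> flexion, n = 592 AF elements
#>   speed ratio (mean, SD): (1.0020, 0.0050)
#>   angular separation (mean, SD): (3.42, 12.29) deg
```

The audit compares, element by element at peak load, the dense direction
maximization of the wave speed against the five-direction approximation:
a mean ratio a few percent above one means the cheap bound underestimates
the true maximum speed only slightly (and hence overestimates the stable
step by the same small margin), while the angular separation measures how
far the chosen propagation direction lies from the true maximizer.
`tidy()`, `glance()` and `autoplot()` methods expose every result as tibbles
and ggplots; `write_mesh()`/`read_mesh()` round-trip Gmsh MSH v4.1 and
legacy VTK files with region labels and fiber vectors.

A thin command-line interface over the same functions is installed at
`inst/cli/ivdfem` (subcommands `mesh`, `simulate`, `audit`, `report`,
`calibrate`).

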