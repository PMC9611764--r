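---
title: "Lumped-parameter FFR modelling in branched coronary arteries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lumped-parameter FFR modelling in branched coronary arteries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffrtree)
```

## The model

`ffrtree` treats a coronary vessel tree as a steady resistive circuit:
pressure plays the role of voltage, volumetric flow the role of current,
and every element is a hydraulic resistance. The inlet is held at the
aortic pressure (90 mmHg by default), every outlet drains to a zero
venous reference through a distal microvascular resistance, and the
fractional flow reserve at any point is simply P(s)/P_in.

Three kinds of elements appear:

1. **Healthy vessel segments** carry the Poiseuille resistance
   R = 128 µ L / (π d⁴), integrated along the sampled lumen profile by
   composite trapezoid quadrature. A configuration flag
   (`neglect_healthy_resistance`) zeroes these, reproducing the common
   circuit idealization in which only stenoses and microvascular beds
   drop pressure; the closed-form solutions below hold exactly in that
   regime, and the default (resistive healthy segments) is the more
   realistic choice for pullback curves.

2. **Stenoses** are nonlinear resistors, dP = C₁q + C₂q², combining a
   viscous loss linear in flow with an expansion (flow-separation) loss
   quadratic in flow. C₁ is computed by the same quadrature over the
   lesion's lumen shape; C₂ = Kt·ρ/2·(1/Aₛ − 1/A₀)² from the healthy
   and minimum lumen areas. The expansion coefficient Kt defaults to
   1.52, the classical empirical value for axisymmetric constrictions;
   blood density ρ is 1050 kg/m³. Both are configurable, and a
   two-point calibration (`calibrate_coefficients`) can replace the
   defaults with an externally characterized lesion.

3. **Outlet microvascular beds** come from a structured-tree model: a
   fractal binary tree rooted at the outlet diameter, daughters scaled
   by α = 0.9 and β = 0.5, branch length γ·d with γ = 25, terminated
   below 50 µm, each branch contributing R = 128 µ γ / (π d³), the
   whole reduced by series/parallel composition. Hyperemia — the state
   in which FFR is defined — is a fixed ×0.24 scaling of the total,
   matching the measured resistance reduction under intravenous
   adenosine at 140 µg/kg/min.

### Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| µ (resistance viscosity) | 0.0035 | Pa·s | high-shear Carreau asymptote, used in all Poiseuille terms |
| Carreau µ₀, λ, n | 0.25, 25, 0.25 | Pa·s, s, — | full shear-thinning law, exposed for rheology work |
| α, β, γ, d_min | 0.9, 0.5, 25, 50 µm | — | structured-tree morphometry |
| hyperemia factor | 0.24 | — | multiplies every structured-tree resistance |
| Kt, ρ | 1.52, 1050 | —, kg/m³ | stenosis expansion loss |
| inlet pressure | 90 | mmHg | aortic boundary condition |

The full Carreau law µ(S) = µ∞ + (µ₀ − µ∞)[1 + (λS)²]^((n−1)/2) is
implemented, but the resistance computations use the constant
high-shear asymptote µ∞ = 0.0035 Pa·s: in a resistance-only network
there is no shear-rate field to evaluate the law at, and coronary wall
shear rates under hyperemia sit well inside the asymptotic regime. The
viscosity entering the structured tree is configurable separately for
sensitivity work.

## Circuit identities

For a single stenosis with distal main resistance R₁ and one branch
with distal resistance R₂ (healthy resistance neglected), the stenosis
flow is the positive root of C₂q² + (C₁ + R_eff)q = V and

- FFR = R₁/(R₁ + R(q)) with R_eff = R₁ when the branch is absent or
  upstream — an upstream branch draws V/R₂ straight from the inlet and
  cannot move the FFR;
- FFR = Rt/(Rt + R(q)) with R_eff = Rt = R₁R₂/(R₁+R₂) when the branch
  is downstream — the parallel bed lowers the effective distal
  resistance, raises the stenosis flow, raises R(q), and lowers the
  FFR twice over.

Under Murray's law the distal resistance scales as d⁻³, so
R₁/R₂ = (d_branch/d_main)³: a branch below one third of the main
diameter shifts Rt by under 4% and is hemodynamically negligible. These
identities are the package's analytic test oracles: the general ladder
solver must reproduce them to 10⁻⁸ relative on the idealized fixtures.

## Numerical choices

- **Quadrature.** Composite trapezoid at a 0.05 mm step. The grid is
  anchored at absolute multiples of the step and always contains the
  profile's own samples and the interval endpoints, which makes the
  integral exactly additive over contiguous sub-intervals. Over a full
  cosine-taper lesion the integrand is periodic and the rule is
  spectrally accurate; over partial intervals it converges at the
  expected O(h²).
- **Stenosis shape.** The lumen area tapers as a cosine-squared bump
  between the healthy shoulders and the minimum-area throat. No
  analytic shape is canonical for a smooth focal lesion; this one is
  symmetric, C¹ at both ends, and reaches the specified minimum area
  exactly. The shape only enters C₁ (weakly) — C₂, which dominates
  severe lesions, depends only on the area ratio.
- **Fixed point, not Newton.** R(q) is affine in q, so freezing R(q),
  solving the linear ladder exactly, and under-relaxing the flows
  (damping 0.5) converges geometrically; the iteration stops when the
  largest relative flow change is below 10⁻¹⁰ (cap 200 iterations,
  all configurable). A converged solution satisfies junction flow
  conservation to round-off because the ladder reduction is exact.
- **Flow direction.** Flows are oriented inlet → outlets and reversal
  is rejected rather than modelled: a steady tree with one pressure
  source and passive resistive outlets cannot reverse.
- **Calibration.** The distal main resistance reproducing a measured
  FFR is found by bisection on log₁₀R₁ over [10⁶, 10¹⁶] Pa·s·m⁻³; FFR
  is strictly increasing in R₁, so the bracket is certified before
  iterating and an unreachable target (e.g. a lesion-free vessel whose
  FFR is pinned at 1) raises a calibration error.

## The synthetic generator

`make_idealized()` reproduces the three benchmark configurations
exactly: 75 mm × 3 mm main vessel, 10 mm lesion of 20% minimum area at
mid-vessel, 2.5 mm branch at 75°, 25 mm proximal or distal of the
throat, 90 mmHg inlet. `make_patient_like()` emulates what an OCT
pullback delivers: a lumen-area profile sampled every 0.2 mm (a
36 mm/s pullback imaged at 180 frames/s), a tapering main vessel,
multiplicative Gaussian area noise (default 2% SD, truncated at ±3 SD —
a stand-in for segmentation jitter), and a seeded random layout of
branches (never below 0.5 mm, the scale ignored at segmentation) and
lesions. Two presets encode the clinically distinct layouts:
`patient1_like` places the lesion distal to the branches (branch flow
barely moves the FFR), `patient2_like` places it proximal to them
(neglecting branches materially overestimates the FFR). All draws come
from one seeded generator, so a seed reproduces a tree byte-for-byte
through the JSON writer.

What the generator does **not** emulate: real OCT segmentation error
structure (correlated along the pullback, worse behind guide-wire
shadows), vessel curvature (a minor FFR effect in this regime),
eccentric or tandem lesion morphology beyond what the cosine taper
expresses, and actual patient microvascular physiology — outlet beds
are morphometric, not measured. Passing tests on synthetic trees
therefore certify the circuit mathematics and the pipeline, not
patient-level predictive accuracy.

## Scope and limitations

The model is steady-state and zero-dimensional: no pulsatility, no
compliance, no wave phenomena, and no 3D pressure recovery distal to a
stenosis — a resistor chain cannot recover pressure, so post-stenotic
FFR is monotone non-increasing by construction. Quantities reported by
3D CFD on patient-specific geometries (e.g. percentage flow shifts for
particular reconstructions) are direction-checked here, not reproduced
numerically: the package asserts their signs and monotonicities, which
are circuit-level facts, at desk scale. Problem sizes throughout the
test suite are small — ladders of a handful of sections, structured
trees of a few hundred distinct states — chosen because every identity
being checked is scale-free.
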