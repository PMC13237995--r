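---
title: "Gap-balanced preoperative planning for TKA: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gap-balanced preoperative planning for TKA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneeplan)
```

## The problem

Conventional total knee arthroplasty (TKA) planning places the femoral
component by bone morphology alone — "measured resection": cut distal and
posterior condyles to the component thickness, set rotation from the
transepicondylar axis (TEA). That guarantees nothing about how the joint
space behaves while the knee moves. In varus knees the medial compartment
stays tight throughout flexion, the implant loads asymmetrically, and
residual imbalance is a recognized driver of pain and loosening.

`kneeplan` implements an in-silico planning pipeline that uses a subject's
recorded flexion kinematics to *balance* the joint: it measures, at every
recorded pose, the medial and lateral gaps between the femoral component
and the tibial resection plane, and searches for the component pose that
equalizes them across the whole flexion arc (0–100°), not only at the
0°/90° poses of conventional gap balancing.

## Coordinate conventions

All geometry lives in a right-handed tibial frame: +x medial, +y anterior,
+z proximal; millimetres and degrees at every API surface. A `rigid_pose`
holds three translations (ML, AP, PD) and three rotations applied in the
fixed order FE → AA → IE about the *tibial* axes:

\[ R = R_z(\mathrm{IE})\, R_y(\mathrm{AA})\, R_x(\mathrm{FE}) \]

FE is flexion about the medial–lateral axis, AA abduction–adduction
(positive = varus) about the anterior–posterior axis, IE internal–external
rotation about the proximal–distal axis. We deliberately use extrinsic
(tibia-fixed) axes rather than a floating-axis decomposition: a constant AA
then means the same coronal tilt — and hence the same medial–lateral gap
asymmetry — at every flexion angle, which is exactly how a fixed varus
deformity presents in recorded weight-bearing kinematics. Varus–valgus
correction of a pose series (`correct_varus_valgus()`) is correspondingly a
pure constant AA offset by the standing HKA angle; the inter-frame steps
are ≤ 10°, so per-DOF linear interpolation is used for resampling.

## Tibial planning: penalized coverage under constraints

The tibial cut plane passes 8 mm below the lateral plateau landmark along
the tibial axis and matches the native posterior slope (no coronal tilt).
The baseplate is then placed on the resection by maximizing the penalized
coverage index

\[ \mathrm{PCI} = \frac{A_I \cap A_T - \mathrm{Sub}(A_I, A_T)}{A_T} \times 100\% , \]

where \(A_T\) is the resection cross-section, \(A_I\) the region enclosed
by the implant underside, and \(\mathrm{Sub}(A_I, A_T)\) the implant area
overhanging the cortex. Two hard constraints apply on top of the area
penalty: baseplate rotation within ±5° of the Insall line, and maximum
boundary overhang ≤ 2 mm (measured as the largest distance from an
outside implant-boundary point to the resection boundary, sampled at
0.05 mm).

The search runs simulated annealing over in-plane translation, rotation and
catalog size: 200 iterations from an initial temperature of 5 (PCI
percentage points), geometric cooling at 0.97/iteration, Gaussian proposals
of 1 mm / 1°, and a 0.1 probability of switching size per move. Infeasible
candidates are rejected outright. These schedule choices complete well
within the iteration budget on this landscape; the suite cross-checks the
result against exhaustive grid search on a coarsened problem (within 1%
PCI over 20 seeded runs) and against the analytic optimum of a concentric
circular toy (where near-greedy annealing, temperature → 0, finds the same
center).

Cross-sections come from an in-package mesh/plane cutter (per-triangle
intersection, undirected segment chaining into loops); overlap areas use
Sutherland–Hodgman clipping, which requires at least one of the two
contours to be convex — true of every contour this pipeline produces
(elliptical trays, plateau slab sections). Degenerate vertex-on-plane
contacts are resolved by nudging the plane 1 nm.

## Femoral planning: MB reference and GB optimization

The morphology-based (MB) plan is the measured-resection reference: distal
cut perpendicular to the femoral mechanical axis at a depth equal to the
distal component thickness below the most distal condyle point, posterior
cut parallel to the TEA at the posterior thickness, component seated on
both cuts and centered on the epicondyles. With thickness-matched cuts the
component restores the native articular surface, so for the synthetic knee
(whose implant shells are zero-offset copies of the bone surfaces) the MB
pose is the identity. The standing deformity is removed from the *motion*
(HKA correction of the kinematics); the synthetic femoral mechanical axis
itself is built neutral, so no second correction is applied on the bone
side.

At each kinematic frame the medial and lateral gaps \(d_m, d_l\) are the
minimum signed distances from the component's medial/lateral condylar
vertices (split by the component midplane; exact-midline vertices belong to
neither) to the tibial resection plane — negative means penetration and is
never clamped. Gap balance is scored by

\[ \mathrm{loss} = \frac{1}{n}\sum_{i=1}^{n} \big|\,|d_l| - |d_m|\,\big|_i \]

over the frames selected by the strategy: the full series (`GB_full`), the
standing frame only (`GB_standing`), or standing plus 90° (`GB_standing_90`).
`GB_full` uses every available frame; the 10° grid is used for reporting.

The pose search is CMA-ES (implemented in `cma_es()`: rank-based weights,
cumulative step-size adaptation, rank-1/rank-µ covariance updates) over a
6-DOF delta around the MB pose, bounded at ±3 mm per translation, ±3° FE,
±8° AA, ±5° IE — wide enough to cover the 0.7°–7.0° range of coronal
corrections the cohort needs, with margin. Candidates outside the box are
clamped and quadratically penalized. σ₀ = 1 on the mixed mm/degree scale,
default population 4 + ⌊3 ln 6⌋ = 9, budget 1800 evaluations, early stop
below 10⁻⁴ mm. Because the loss is exactly flat in some directions (a pure
proximal–distal shift moves both gaps equally), a tiny quadratic pull
toward the MB pose (weight 10⁻⁴) acts as a tie-break so flat directions do
not wander; the reported loss is always the plain mean gap difference, and
the result is never worse than the MB start (elitism). The insert
recommendation is the largest catalog thickness not exceeding the smallest
gap anywhere in the profile (ties resolved toward thinner to avoid
over-stuffing); if nothing fits, the thinnest insert is returned flagged.

### What a rigid component can and cannot correct

One geometric fact shapes the results and is worth stating precisely. The
synthetic condyles are equal spheres centered on the flexion axis. A
constant (tibia-fixed) varus offset \(\alpha\) in the kinematics produces a
constant gap asymmetry \(s\sin\alpha\) (s = condyle spacing). A component
rotation, however, is femur-fixed: its effect on the gap differential is
\(s(\sin\delta_{AA}\cos\theta + \sin\delta_{IE}\sin\theta)\) at flexion
\(\theta\) — a pure sinusoid over the arc. No fixed rotation reproduces a
constant, so full-arc balance of a constant deformity has a nonzero floor:
the optimum splits the correction between varus–valgus (≈ 0.7 α, dominant
at low flexion) and external rotation (≈ 0.8 α, dominant in flexion),
leaving a residual loss of about \(0.1\, s \sin\alpha\) — some 0.3–0.6 mm
for this cohort, comfortably below 1 mm but not zero. The *total*
rotational correction tracks the injected deformity essentially 1:1. This
mirrors surgical practice, where coronal alignment corrects the extension
gap and femoral rotation the flexion gap; on real, non-spherical anatomy
the split differs but the principle stands. Consequently, a test that
expects the AA delta alone to equal the injected varus within 0.5° cannot
pass under this generator; the suite instead verifies the invariants the
geometry actually guarantees.

## Ligament model

Three collateral bundles are modeled: the anterior and posterior bundles
of the superficial MCL and the intermediate LCL bundle, with stiffnesses
k = 2500 / 3000 / 2000 N and strain constant ε₁ = 0.03. Bundle length at
each frame is the shortest wrapping path from the femoral attachment
(moved by the frame pose) to the tibial attachment around the bone (and,
in implanted mode, implant) surfaces: when the straight segment clears all
obstacles its Euclidean length is used exactly; otherwise a visibility
graph over clearance-offset surface vertices (connected along mesh edges,
plus endpoint sight-lines) gives an initial path that iterative
rope-shortening with re-projection tightens toward the geodesic. Against
the closed-form tangent–arc–tangent wrap of a sphere the solver is within
1%.

Strain is ε = (L − L₀)/L₀ with L₀ the 0°-flexion length *of the same mode*
(native or implanted) — the reference is mode-local, so implanted-mode
strains measure change relative to the implanted 0° state. Force follows
the piecewise nonlinear law

\[ f(\varepsilon) = \begin{cases}
  0.25\,k\,\varepsilon^2/\varepsilon_1 & 0 \le \varepsilon \le 2\varepsilon_1 \\
  k(\varepsilon - \varepsilon_1) & \varepsilon > 2\varepsilon_1 \\
  0 & \varepsilon < 0 ,
\end{cases} \]

continuous and once-differentiable at ε = 2ε₁ (value kε₁, slope k). The
rig tension protocol adds these forces to side baselines — 130 N medial
(aMCL and pMCL share the medial baseline), 100 N lateral — per 10° test
angle; slack bundles apply the bare baseline. Viscoelasticity, cruciates
and capsule are out of scope.

## The synthetic knee

The generator stands in for CT and biplane-fluoroscopy data and defines the
study conditions:

* femoral condyles: two equal spheres, radius 22 mm, centers 46 mm apart on
  the flexion axis; the femoral component is a zero-offset shell of them.
  Equal spheres keep an analytic gap oracle (asymmetry = spacing · sin
  varus); the native "medial tight / lateral lax" laxity pattern is
  deliberately not modeled.
* tibia: slightly dished elliptical slab, 75 × 50 mm, with elliptical
  baseplate catalog (ML widths 58–70 mm, 9 mm thick); component thicknesses
  default to 9 mm (no vendor geometry is published for the reference
  implants, so the catalog is invented).
* landmarks: epicondyles just beyond the condylar spheres, Insall line
  along the tibial AP axis, ligament attachments placed so native bundle
  lengths and their flexion trends are anatomically plausible (aMCL ≈ 86 mm
  lengthening by ~4 mm to 70°, pMCL ≈ 102 mm shortening by ~10 mm, iLCL
  ≈ 61 mm slightly shortening).
* kinematics: weight-bearing lunge 0–100° in 10° frames; AA carries the
  standing HKA (default 2°, removed by correction) plus the injected
  kinematic varus (cohort draws uniform in 0.7°–7.0°, the range of coronal
  corrections observed clinically in this setting); small smooth posterior
  rollback (−3 mm · sin(θ/2)) and internal-rotation drift (0.5° · θ/100);
  proximal–distal translation keeps the tighter condyle in contact with the
  plateau. An optional zero-mean smooth AA perturbation (default amplitude
  0) is available for robustness experiments, so default runs are exactly
  deterministic given the seed.
* native posterior slope: 5°, matched by the tibial cut.

What passing tests on this geometry do **not** show about real data:
irregular resection contours (synthetic coverage reaches ~87% PCI where
irregular anatomy yields ~77%), asymmetric condylar shapes, cartilage and
menisci, soft-tissue releases, and measurement noise in registered
kinematics. The pipeline's claims on synthetic knees are about the
*machinery* — constraint handling, optimizer behavior, formula fidelity —
not about clinical effect sizes.

## Numerical choices and degenerate inputs

* Mesh cutting nudges the plane by 10⁻⁹ mm on exact vertex contact; loops
  with fewer than 3 points are discarded; a plane missing the mesh returns
  an explicitly empty contour.
* `polygon_areas()` errors on non-coplanar input (tolerance 10⁻⁶) and on
  two non-convex contours.
* Wrapping offsets surface sample points by max(0.1 mm, 1.2% of the
  obstacle half-extent) along vertex normals; path tightening keeps a
  0.02 mm clearance; endpoints inside an obstacle are an error.
* Seeds: every stochastic stage (cohort draw, SA, CMA-ES) takes its seed
  from `split_seed(global, subject, stage)`, a small string hash folded
  into the global seed and kept below 2³¹, so subjects are independently
  reproducible and whole pipeline runs are byte-identical under a fixed
  seed.
* Problem sizes used by the test suite and the acceptance script — 8
  subjects, 11 frames, ~1000-vertex component meshes, 1800 CMA-ES
  evaluations, 200 SA iterations — were chosen as the smallest sizes at
  which the optimizers are comfortably converged; the full suite runs in a
  few minutes on one core.

## Known limitations

Single-radius spherical condyles (see the correction-split discussion
above); no femoral sizing; no keel/peg or cementing checks; no
patellofemoral joint; AA-only varus–valgus correction of kinematics (the
simplest reading of a single scalar HKA input — whether translations should
also be corrected is an open question we documented rather than guessed);
rotation interpolation per Euler DOF (fine at ≤ 10° frame spacing); the
wrapping solver connects surface nodes along mesh edges and endpoint
sight-lines, which is exact for single-obstacle wraps but may shortcut
multi-obstacle weaves; `GB_standing` with one frame balances that frame
only, by construction.
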