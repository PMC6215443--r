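---
title: "Inferring bipedal hindlimb posture from cancellous bone fabric: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring bipedal hindlimb posture from cancellous bone fabric}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trabpose)
```

## The scientific problem

Cancellous (trabecular) bone remodels so that its strut architecture
tracks the principal stress directions of habitual loading — the
trajectorial hypothesis.  Run in reverse, this gives a way to interrogate
locomotion in animals that can no longer be watched: if we can compute,
for a candidate limb posture, the compressive principal stress axes
($\sigma_3$) throughout the hindlimb bones, then the posture whose stress
axes best align with the measured primary fabric axes ($u_1$) is a
time-and-load-averaged *characteristic posture* for that animal.  It is
not any single instant of a stride, but in extant birds the analogous
solution posture resembles mid-stance.

`trabpose` implements this reverse pipeline end to end at desk scale:

1. **A parameterized single-hindlimb model** — pelvis (fixed), femur,
   tibiotarsus, tarsometatarsus and pes, with a 3-DOF hip, hinge knee,
   ankle and metatarsophalangeal (MTP) joint: six actuated degrees of
   freedom.  Thirty-three musculotendon actuators follow the standard
   archosaurian roster (IT1…FB), each with an activity flag and a
   maximum force of **two body weights**; a reserve actuator at the MTP
   joint absorbs residual moment demand there.
2. **Quasi-static inverse statics + static optimization** — a vertical
   ground reaction force of one body weight at a centre of pressure 40%
   along the pes, plus segment weights, determine the net joint moments;
   muscle activations $a_i \in [0,1]$ are found by minimizing
   $\sum a_i^2$ subject to moment balance.
3. **A beam-theory bone-loading surrogate** — internal axial force,
   bending moments and torque along each bone from free-body closure;
   hollow-ellipse section stresses; principal stress axes per lattice
   point.  Within the epiphyses the compressive axis is the direction of
   the joint resultant force (see "Surrogates" below).
4. **Axial correspondence machinery** — orientation-tensor mean axes
   inside anatomically placed spheres, angular deviations
   $\arccos|a \cdot b|$, an unweighted mean score, stereonet projection.
5. **A greedy posture search** that mirrors the manual posture iteration
   of the original workflow, stopping when no candidate improves the
   score.
6. **A synthetic-data generator** with known ground truth, so the whole
   pipeline is testable without any fossil data.

## The stated world of the synthetic generator

The generator's defaults are the conditions printed for the three
modelled scales, with documented choices where no value is printed:

| Quantity | Large tyrannosaurid scale | Troodontid scale | Chicken scale |
|---|---|---|---|
| Total body mass (kg) | 2757 | 48.5 | 1.56 (back-derived) |
| Right hindlimb mass (kg) | 342.7 | 5.65 | 10% of total |
| Pelvis segment mass (kg) | 2414.3 | 42.85 | total − limb |
| Femur length (m) | 0.984 | 0.304 | 0.075 |
| Pelvis COM anterior of hip (m) | 0.423 | 0.168 | isometric rescale |
| MTP reserve ceiling (N·m) | 1,767,308 | 31,090 | 1,000 |

The chicken-scale mass is never printed; it is implied by the stated
mass-proportionality of the reserve actuator (1,000 N·m : 1,767,308 N·m
as mass : 2757 kg → 1.560 kg) and is documented as a default, not a
source value.  The printed per-muscle force caps (54,073.9 N / 951.2 N)
differ by ≈0.03% from 2·m·g computed from the printed masses; the package
computes from the printed masses.

Unprinted geometry is filled with fixed, documented defaults chosen once:
segment-length ratios per scale (e.g. tibiotarsus/femur = 1.0 at
tyrannosaurid scale, 1.3 at troodontid scale, 1.4 at chicken scale,
reflecting increasing cursoriality), limb-mass split 60/30/7/3% across
femur/tibiotarsus/tarsometatarsus/pes, mid-shaft outer radius 5–8% of
femur length with cortical wall fractions 0.25–0.35, and procedurally
generated 3-D muscle paths (origin, via points, insertion) in
segment-local frames.  Retinacular via-point depths (patellar ridge 2.4
femoral radii, hypotarsus 2.8 tibial radii) were set so the two-body-
weight force caps make the reference postures solvable with headroom;
they were fixed before the acceptance experiments and not revisited.

**Fabric noise model.**  Fabric axes are sign-free, so noise is drawn
from the Watson bipolar distribution, density
$\propto \exp(\kappa (\mu^\top x)^2)$, by rejection from the uniform
sphere — the simplest axial analogue of "mean direction" statistics.
$\kappa = \infty$ is the zero-dispersion sentinel (axes equal the modal
axes exactly).  Each bone volume is an idealized capsule (cylinder plus
hemispherical epiphyseal caps, cap radius 2.2 mid-shaft radii), latticed
at 1/40 femur length.  All fabric coordinates and axes live in
**bone-local (material) frames**, which is what makes a fabric field a
property of the bone rather than of any one posture.

**What a green test does and does not establish.**  The generator
emulates the *statistical structure* of fabric data — axes concentrated
about the stress axes of a hidden true posture, sampled on a lattice,
with anatomically placed spherical ROIs.  It does not emulate real
trabecular anisotropy gradients, inter-individual variation, diagenetic
bias, or any disagreement between bone adaptation and the quasi-static
model family.  Recovery of the generating posture therefore validates the
*pipeline* (identifiability, statistics, optimization, bookkeeping), not
the biological hypothesis.

## Surrogates replacing the finite-element stage

The published workflow solved continuum FE models of fossil geometry.
At desk scale this package substitutes:

* **Shaft**: beam theory.  At a lattice point at radius $r$, the stress
  state is the axial normal stress ($N/A$ plus bending) and the
  torsional shear $T r / J$; transverse-shear contributions to the
  trajectory directions are neglected.  The principal axes of this
  planar state are closed-form; pure compression gives $\sigma_3$ along
  the long axis, pure torsion a 45° helix.
* **Epiphyses**: the compressive axis is the unit direction of the joint
  resultant force transmitted through that epiphysis, and the tensile
  axis is orthogonal to it within the plane it spans with the bone long
  axis.  This is *our construction* (published trajectory figures do not state
  how epiphyseal directions arise in the FE models) and is labelled as
  a surrogate wherever it appears.  The distal pes cap uses the ground
  reaction force direction.

These preserve exactly the quantities the method scores — principal axis
*directions* and the mid-shaft loading metrics — while remaining cheap
enough to evaluate hundreds of candidate postures.

### Mid-shaft metrics

* $\sigma_\mathrm{bending}$ is the bending amplitude of the extreme
  fibre stresses.  When the extremes straddle zero (the planar-bending
  regime), this equals $(|\sigma_{\max}| + |\sigma_{\min}|)/2$; under
  pure axial load it is 0 and the state is flagged degenerate.
* The principal-stress inclination from the local long axis is
  $\tfrac12\,\mathrm{atan2}(2\tau, \sigma)$, computed for both principal
  axes, each folded into [0°, 45°], then averaged: 0° in pure bending,
  45° in pure torsion.
* The local long axis itself comes from a damped Gauss–Newton cylinder
  fit to mid-shaft points (window: middle 20% of the shaft), with the
  mid-shaft section plane normal to the fitted axis.
* The neutral-axis angle is reported in [−90°, 90°] from the
  mediolateral axis.

## Numerical choices

* **Static optimization.**  Minimize $\sum a_i^2$ (the exact objective of
  the original modelling stage is not restated; quadratic effort is the
  standard choice, and recruitment-sharing differences are covered by the
  property suite).  The QP (equality rows, box bounds) is solved by a
  small active-set projection solver written for this package (no QP
  library exists in the supported stack), validated against brute-force
  and penalty oracles.  The MTP reserve is costless and enters only the
  MTP row, so that row never constrains the muscles: the QP runs on the
  other five DOFs and the reserve absorbs the MTP remainder (erroring if
  the ceiling — set at ≥27 body-weight·limb-lengths in the published
  models — would be exceeded).  Equilibrium residuals are held to
  $10^{-6} \times$ body weight × hip height.
* **Moment arms** are tendon-excursion derivatives $r = -dL/d\theta$ by
  central differences (step $10^{-4}$ rad), which guarantees sign
  consistency with the virtual-work inverse statics.
* **Mean axes** are principal eigenvectors of the orientation tensor.
  For concentrated data this agrees with a sign-consistent vector mean; ties between leading eigenvalues are broken by the
  lexicographically smallest representative and flagged.
* **Degenerate inputs**: zero stress states, empty axis sets, zero-area
  sections, sub-minimum ROI occupancy and infeasible postures all raise
  explicit errors or flags rather than returning silent numbers.

## The posture search

Greedy descent with fixed 5° steps mirrors the 5–6 hand-iterated
postures of the original study; a full optimizer is deliberately not
promised.  One deviation from plain coordinate descent proved necessary:
several correspondence signals depend on *segment orientations*, which
are sums of joint angles, so the score surface contains diagonal valleys
(hip extension trades off against knee flexion almost one-for-one).
Pure single-DOF steps stall on the valley wall short of the optimum —
observed concretely on zero-noise synthetic fabric, where the search
plateaued at ≈2° mean deviation one step per DOF away from the truth.
The proposal set therefore adds all two-DOF diagonal steps.  With them,
the zero-dispersion experiment recovers the generating posture exactly
and the κ = 50 Monte-Carlo experiment recovers it to within one step per
DOF.  Ties are broken by smallest total angular change, then DOF order;
plateaus terminate the search; all randomness is confined to fabric
generation.

The hip-articulation variant mechanism translates the femur (and all
distal structures, including muscle points at or below hip level)
medially within the acetabulum and adds fixed abduction / external
long-axis-rotation offsets, recomputing step-width and hip-height
diagnostics — the printed variant parameters (50 mm, 14°, 27°) run
end-to-end in the test suite.

## Reported cross-species parameters

For a solved posture the package extracts, per species: whole-body COM
anterior offset normalized by total leg length; hip and knee angles; the
degree of crouch $1 - h/h_\mathrm{max}$ (with $h_\mathrm{max}$ the summed
femur + tibiotarsus + tarsometatarsus lengths — our operationalization
of a quantity usually plotted without a formula; empirical crouch
regressions are out of scope); mid-shaft principal-stress inclination,
shear/bending ratio and neutral-axis angle; and normalized muscle moments

$$M^* = \frac{a\,F_{\max}\,r_i}{m\,g\,h},$$

summed over the hip-abductor group (iliofemoralis externus) and the hip
medial-rotator group (iliotrochantericus caudalis and
puboischiofemorales interni 1–2 at fossil scales; the iliotrochanteric
actuator alone at chicken scale, where the iliofemoralis externus is
inactive).  $M^*$ is dimensionless by construction and the suite verifies
invariance under a uniform ×10 geometric / ×1000 mass rescaling.  Strict
monotonicity checks across the basal → derived → extant ordering
implement the gradual-change assessment; with $n = 3$ templates this is
a coarse trend report, not an inferential test.

## Known limitations

* The two-body-weight force cap makes deep crouches genuinely infeasible
  for the large template — a real property of the model family, handled
  by the search skipping infeasible candidates; base postures should be
  chosen inside the feasible region.
* Beam + joint-resultant surrogates cannot reproduce double-arcuate
  epiphyseal trajectory patterns; only mean directions within ROIs are
  scored.
* No dynamics, tendon elasticity, force–length/velocity effects,
  biarticular co-contraction accounting, or pelvis mobility.
* The crouch index clamps at 0 near the columnar posture where toe-
  standing transiently raises the hip.
* Small-step angular identifiability of the MTP angle requires fabric in
  the pes; the generator lattices it for exactly that reason.
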