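---
title: "Simulating bony hip range of motion and impingement after THA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating bony hip range of motion and impingement after THA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipsweep)
```

## The model

After total hip arthroplasty (THA), the bony range of motion (BROM) of a hip
is the largest single-plane rotation of the femur (with its implanted stem
and head) before any part of the femoral side touches any disallowed part of
the acetabular side. `hipsweep` computes this limit by direct geometric
simulation:

1. **Coordinate frames.** A pelvic coordinate system (PCS) is built from the
   two anterior superior iliac spines (ASIS), the two pubic tubercles and the
   hip joint centre (HJC): the mediolateral X axis runs from the left to the
   right ASIS, the anteroposterior Y axis is the normal of the anterior
   pelvic plane (APP, the plane through both ASIS and the pubic-tubercle
   midpoint), and Z completes a right-handed frame. A femoral coordinate
   system (FCS) takes its longitudinal axis from the knee centre to the HJC
   and its mediolateral axis from the epicondylar line, orthogonalised.
   Both frames originate at the HJC.
2. **Neutral alignment.** Both bodies are rigidly moved so the two frames
   coincide with the world frame (X to the patient's right, Y anterior, Z
   superior). In this pose elementary world-axis rotations generate the
   clinical motions: Rx is flexion-extension, Ry abduction-adduction, Rz
   internal-external rotation.
3. **Implant placement.** The cup and liner, supplied in a canonical pose
   (centre at the origin, opening axis +Z), are rotated onto the cup axis
   derived from radiographic inclination/anteversion (Murray's definitions,
   relative to the APP) and translated to the HJC. The head is centred on
   the HJC; the stem is seated along the neck axis at the analytic
   cone-in-cone taper depth, backed off by a small clearance (default
   0.001 mm) so the seated surfaces do not register as intersecting.
4. **Pelvic tilt.** A tilt condition rotates the pelvis-side body (pelvis,
   cup, liner) about world X; anterior tilt is positive. Because flexion and
   extension are rotations about the same world axis, a tilt of `t` degrees
   shifts the flexion limit by exactly `-t` and the extension limit by `+t`
   (up to the sweep grid): the collision configuration depends only on the
   relative pelvis-femur rotation. This exact coupling is the central
   mechanical fact the package demonstrates, and it holds for *any*
   geometry, which is why a synthetic cohort can stand in for patient CT
   data when testing it.
5. **The sweep.** For each motion the femoral side is rotated in 0.5 degree
   increments (a pre-rotation of 90 degrees flexion precedes the internal
   rotation sweep, IR@90Flex) until a monitored mesh pair collides. The
   reported limit is the *last collision-free* angle - the conservative
   reading of an incremental search. Sweeps are capped (180 degrees;
   150 for axial rotations) and a capped sweep reports type `NONE`.
6. **Classification.** The colliding pair determines the impingement type:
   implant-implant (ITII), implant-bone (ITBI) or bone-bone (BTBI). When
   several categories first collide at the same grid step, the fixed
   priority ITII > ITBI > BTBI applies. Monitored pairs are liner/cup
   against stem/femur, and pelvis against stem/head/femur; the articulating
   head-liner and head-cup pairs and the same-side fixation pairs
   (cup-pelvis, stem-femur, head-stem) are excluded as intentionally in
   contact or interpenetrating.

Left hips are mirrored across the sagittal plane into a canonical right-hip
frame before simulation (one code path, checked by a mirror-invariance
test).

## Collision detection

Collision queries use a triangle-triangle intersection predicate under an
axis-aligned bounding-box hierarchy (AABB tree, deterministic median split
on the longest centroid axis, leaf size 4). Design choices:

* **Closed triangles**: touching counts as intersecting, with a tolerance of
  1e-10 on scaled coordinates; ties resolve toward "intersecting". This is
  the conservative convention for an impingement detector driven by a
  discrete sweep.
* **Surface intersection only**: no containment query. The sweep starts
  from a verified collision-free pose and advances in 0.5 degree steps, so
  a body cannot pass fully inside another between steps at anatomical
  scales; this is a documented limitation, not a checked invariant.
* A brute-force all-pairs path (`brute_force_collide`) exists solely as the
  independent oracle; the test suite checks 100% agreement over hundreds of
  randomized poses, and an R-level separating-axis implementation
  independently cross-checks the triangle predicate.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| sweep step | 0.5 | deg | grid of the incremental search; limits are multiples of it |
| sweep cap | 180 (150 axial) | deg | beyond it a motion reports `NONE` |
| pelvic tilt range | (-60, 60) | deg | validated posing range; outside it is an error |
| head diameter | 32 | mm | cohort-standard prosthetic head |
| articulating clearance | 0.05 | mm | liner inner radius minus head radius |
| taper seat clearance | 0.001 | mm | axial back-off from exact cone tangency |
| cup inclination / anteversion | 40 / 20 | deg | radiographic angles, APP reference |
| BVH leaf size | 4 | triangles | determinism/speed trade-off only |

## The synthetic data generators

No patient geometry ships with the package; three generators replace it.

**Analytic ball-in-cup fixture** (`make_analytic_ball_cup`): a spherical
head in a spherical cup shell with rim `coverage` degrees beyond the
hemisphere and a cylindrical neck along the cup axis. Its limiting angle has
the closed form `90 - asin(r_neck / r_head) - coverage` for every planar
sweep, which makes it the independent oracle for the whole sweep pipeline;
tests require agreement within one 0.5 degree step over a 5 x 5 parameter
grid.

**Parametric hip** (`make_parametric_hip`): watertight star-shaped and
lathed surfaces - a bony acetabular margin shell with anterior (AIIS-like)
and ischial prominences, a resected femur with trochanteric bumps, and the
implant set. The prominences are aimed at the azimuths where the neck path
crosses the bony margin in deep flexion and in extension, so the bony rim
competes with the liner rim exactly where it does anatomically. With the
default 14 mm prominences the model flexes to 126.5 degrees before
anterior bone contact (ITBI) and extends to 53.5 degrees; enlarging the
anterior prominence monotonically lowers the flexion limit. These defaults
were chosen once to give limits in a plausible post-THA range and mixed
impingement types; they are deliberately more mobile than a typical patient
cohort since no soft tissue is modelled (the outputs are BROM, not
functional ROM).

**Tilt cohort** (`generate_cohort_pt`): standing pelvic tilt preoperatively
`N(18.9, 8.8^2)` degrees, chained with independent normal changes of
`-4.8 +/- 6.0` (to 6 months) and `+0.6 +/- 6.9` (6 to 12 months), clipped
to [-30, 50]. Only these first and second moments are calibrated;
between-timepoint correlation beyond the chaining, and any dependence of
tilt on anatomy or cup position, are not modelled because they are not
reported. `generate_synthetic_cohort` pairs each tilt triple with jittered
anatomy and cup angles (inclination 40 +/- 6, anteversion 20 +/- 6 degrees,
offset 47 +/- 4 mm), regenerating any clearance-infeasible draw from the
next RNG substream.

What passing tests on this synthetic cohort do show: the sweep mechanics,
the exact tilt-flexion/extension coupling, the classification logic and the
statistics layer. What they do not show: agreement with any real cohort's
ROM magnitudes, regression tables or impingement-type percentages - those
depend on patient-specific CT geometry.

## Numerical choices and degenerate inputs

* Geometry is in millimetres; angles cross the API in degrees.
* Rotations must be orthonormal with determinant +1 to 1e-9; frames are
  validated right-handed.
* STL readers merge duplicated facet corners at 1e-6 mm; degenerate
  (zero-area) triangles are a validation error naming the faces.
* Rigid registration (`rigid_best_fit`) is the closed-form SVD solution on
  given correspondences; collinear sources are rejected as
  underdetermined. Iterative surface registration is out of scope.
* The regression layer reports `RMSE = sqrt(SSE / n)`; the denominator is
  configurable to `n - 2` since conventions differ.
* Clinical-relevance boundaries 10 and 20 degrees both belong to the
  `medium` category (the published rule brackets "10 to 20" inclusively).
* Category shares in shift tables are computed over patients - each
  patient contributes one impingement type per motion and condition.
* A start pose that already collides (extreme tilt, or IR@90Flex when the
  90 degree pre-flexion itself impinges) is an error carrying the witness
  pair, not a zero result.

## Problem sizes

The default parametric model carries roughly 600-800 triangles per
component, enough that discretisation error on the fixture grid stays well
inside the 0.5 degree sweep step. The bundled analyses use cohorts of 20
synthetic models (the regression checks) and 56-5000 tilt draws (the
statistical checks); all are regenerated from seeds at run time.

## Known limitations

* Single-plane motions about world-fixed axes only; combined motions and
  body-fixed sweep axes after the IR pre-flexion are not simulated (the
  world-fixed reading is a configuration choice; a body-fixed variant would
  change IR@90Flex limits).
* Static tilt per condition; no dynamic pelvic motion during activities.
* No soft tissue: limits are bony/implant ROM and overestimate functional
  ROM.
* Surface-based collision without penetration depth or minimum-distance
  queries.
* The synthetic anatomy is a mechanism model, not a shape model; it does
  not reproduce patient-level ROM distributions.
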