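---
title: "Bone-centered 3D angular measurement of the canine tibia: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bone-centered 3D angular measurement of the canine tibia: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tibia3d)
```

## The measurement problem

Angles between anatomical axes of a long bone are well defined only within
a plane. The axes the canine tibia offers — the proximal caudal
retrocondylar tangent, the distal cranial antecochlear tangent, and the
proximal and distal mediolateral joint-surface axes — are skew lines in 3D:
they neither intersect nor are parallel, so they form no angle until they
are projected into a shared plane. Radiography performs that projection
implicitly, with a plane dictated by how the limb was positioned;
`tibia3d` performs it explicitly, in planes anchored to the bone itself, so
the result cannot depend on scanner pose.

## The bone-centered frame

From a validated landmark set (ten named points, coordinates in mm, any
Cartesian scanner or patient frame):

1. `ez = unit(PTC − DTC)`, the total tibial longitudinal axis, with the
   distal shaft center `DTC` as origin. The transverse plane is the plane
   through the origin perpendicular to `ez`.
2. `ey` is the retrocondylar direction `unit(TRCAx_lat − TRCAx_med)`
   (always stored medial to lateral) orthogonalized against `ez` by
   Gram–Schmidt. A literal "parallel translation" of the retrocondylar axis
   cannot serve as the second axis of an *orthogonal* system unless it
   happens to be perpendicular to `ez`; removing its longitudinal component
   is the unique choice that preserves the axis's orientation within the
   dorsal plane while honoring orthogonality. The dorsal plane is oriented
   by this axis.
3. `ex = ey × ez` completes the frame (sagittal-plane normal is `ey`,
   dorsal-plane normal `ex`).

The stored frame is right-handed (`det[ex ey ez] = +1`) for both sides.
Side enters the readout in two deliberately different ways:

- **Torsion** is measured as the signed angle about `ez` from the projected
  retrocondylar to the projected antecochlear direction, multiplied by a
  side sign (+1 right, −1 left). An external twist of a left tibia is the
  mirror image of an external twist of a right tibia, and a mirror
  reflection negates signed angles; the side sign restores one numeric
  convention — readouts above 180° are external — for both sides.
- **Varus/valgus** needs no explicit side handling: the dorsal-plane
  normal `ex` is a cross product, hence a pseudovector that flips
  orientation under reflection by itself. The signed angle about `ex`
  between the projected joint-surface axes is therefore mirror-consistent
  as is, with valgus positive on either side. (The angle between the
  projected joint-surface axes equals the angle between their in-plane
  perpendiculars — the proximal and distal tibial longitudinal axes one
  would draw — so the perpendiculars are never constructed.)

Both conventions are locked in by a property test: mirroring any landmark
set across a paramedian plane and flipping its side label reproduces the
readouts and the direction labels exactly.

## Readout convention

Neutral is 180°: parallel projected axes. The stored measurement keeps full
double precision; readouts are rounded to 0.1° only at the presentation
layer, matching the reporting resolution of the validation tables. The
direction label (`internal`/`external`, `varus`/`valgus`) switches to
`neutral` when the signed deviation is below 0.05°, half the reporting
resolution. Validation deformities span readouts of roughly 90°–270°
(±90° of torsion); values outside (0°, 360°) are rejected in measurement
tables.

## Tolerances and degeneracies

- Degeneracy detection (axes near-parallel to a plane normal, frame axes
  near-parallel) uses a relative threshold of 1e-6; post-conditions
  (orthonormality, rigid-motion invariance, exact deformity recovery) are
  asserted at 1e-9 to 1e-12. With mm-scale coordinates in double precision
  these leave several orders of magnitude of headroom.
- A torsion of ±90° makes the distal joint-surface axis parallel to the
  dorsal-plane normal: its projection vanishes and the varus/valgus angle
  raises a classed degenerate-projection error naming the offending axis,
  rather than returning an arbitrary value. The torsion angle remains well
  defined there.
- Landmark validation enforces the closed name vocabulary, finite
  coordinates, `DTC`–`PTC` separation above 1 mm and medial/lateral pair
  separation above 0.1 mm; readers convert RAS-declared coordinates to the
  internal LPS convention by negating the first two components (a proper
  rotation, so no side or sign logic is triggered).

## The synthetic tibia

`tibia_template()` generates a neutral landmark set in canonical pose: long
axis on +z, caudal on +y, all four mediolateral axes parallel, left bones
as exact mirror images. Default dimensions (bone length 180 mm, condylar
width 32 mm, cochlear width 20 mm, retrocondylar offset 12 mm caudally,
antecochlear offset 8 mm cranially, shaft centers at 0.25/0.75 of bone
length) are plausible for a medium-sized dog; since the measured angles are
provably independent of all of them (a tested size-invariance property),
the template claims no anatomical fidelity — it is a geometric phantom with
known ground truth.

The deformity operators mirror a physical validation model:

- `apply_torsion()` rotates the distal landmark group (antecochlear
  endpoints, cochlear groove centers, and `DTC`, which lies on the axis and
  is unchanged) about the shaft line, emulating a mid-diaphyseal cut with a
  rotational hinge. `hinge_level` is parameterized as the fraction along
  the `DTC`→`PTC` segment (default 0.5); for the default template this
  coincides with the mid-diaphyseal level, and for torsion the hinge
  position is immaterial anyway because the rotation axis is the whole
  shaft line.
- `apply_frontal_angulation()` rotates the same distal group about the
  craniocaudal axis through the hinge point, valgus positive. This enables
  a ground-truth check of the varus/valgus angle that no physical reference
  standard provides.
- `apply_rigid_pose()` applies x-tilt, then y-tilt, then axial spin about
  the set centroid, then a translation; the presets `oblique15`/`oblique45`
  reproduce the double-oblique scanner poses of the positioning experiment.
  The rotation order is a fixed documented convention — any rigid motion
  leaves the measurements invariant, so the order only matters for
  reproducing a specific pose.
- `jitter_landmarks()` adds isotropic Gaussian placement noise per
  landmark. With the default template, 0.3 mm of placement noise yields a
  torsion-readout standard deviation of order one degree (the Monte-Carlo
  run in the suite measures ≈1.46°, dominated by the short 20 mm distal
  axis: √2·0.3/20 rad ≈ 1.2°), the same order as observer variability on
  real data; the asserted band (0.1°–1.5°) comes from this simulation, not
  from any published value.

Exact recovery holds for *pure* deformities: applying θ of torsion (|θ| <
90°) or φ of frontal angulation (|φ| ≤ 30°) to the template changes the
corresponding readout by exactly θ or φ (to 1e-9°) and leaves the other at
180°. Combined deformities couple weakly — each hinge is defined on the
already-deformed bone, so applying 20° torsion then 5° angulation reads
(200.017°, 185.000°) rather than (200°, 185°) — which is faithful to how a
real bone deforms; the worked-example assertions therefore hold at the
0.1° reporting resolution while the pure-deformity assertions hold at
1e-9°.

## Statistics

- `bland_altman()` summarizes paired differences `d = y − x` (test minus
  reference) by their mean (bias), sample SD, and 1.96·SD limits of
  agreement. The accuracy headline is reported as |bias| at 0.1°
  resolution.
- `passing_bablok()` implements the classic non-parametric
  method-comparison regression: all pairwise slopes (pairs with equal x
  contribute none; slopes of exactly −1 are discarded), slope = the median
  of the sorted slopes offset by the count of slopes below −1, intercept =
  median of `y − slope·x`, confidence intervals from the rank-based normal
  approximation with half-width `z₀.₉₇₅·√(n(n−1)(2n+5)/18)`. Tie medians
  use the midpoint of the central order statistics. The suite checks it
  against a brute-force all-pairs oracle on hundreds of random small
  instances; scale equivariance of the slope is exact only when all
  pairwise slopes are positive (the −1 offset count is not
  scale-invariant), and is tested on such concordant instances.
- `within_subject_cv()` is Bland's CV for repeated measurements: for
  duplicates the within-subject variance is `(v₁ − v₂)²/2`, and the CV is
  the root mean square of per-subject SD/mean ratios, graded excellent
  (<3%), good (<10%), moderate/fair (<15%), poor (≥15%) on half-open bins.
  The inter-observer pairing defaults to observer 1's *first* occasion
  against observer 2 (the pairing is configurable since a study may not
  state it).
- `position_difference_table()` implements the positioning subtraction
  analysis: per bone and pose the mean of all readings (here: observer 1
  twice, observer 2 once — the three-reading mean is what reproduces the
  published biases to 3 decimals), then per-bone differences between poses,
  summarized by their mean (BIAS) and a two-sided one-sample t-test against
  zero. The choice of t-test is a documented judgment call — the source
  analysis names only the Bland–Altman framework for the bias — so the
  p-values are diagnostics, not replication targets.

## Packaged validation data

Two measurement tables ship with the package as plain CSV:

- `torsion_model_data()`: 13 paired goniometer/CT readouts of a physical
  torsional deformity model (presets 0, ±10…±50, ±90° from the anatomical
  situation). Note the model's "0° (normal)" reads 189.5°: the intact bone
  itself carries ≈9.5° of external torsion, which is why the synthetic
  template (neutral by construction) complements rather than replaces these
  data.
- `positioning_data()`: 360 readouts of the positioning experiment
  (20 bones × 3 scanner poses × 3 readings × 2 angles). The data are kept
  digit-for-digit verbatim, including one anomalous varus/valgus value
  (132.2° — ~50° away from every other reading of that bone, most likely a
  transcription slip in the source table). It is retained because the data
  are the data; it dominates the TVA inter-observer CV (3.02%), which is
  therefore interpreted with caution, while the intra-observer CVs and the
  TTA inter-observer CV are unaffected.

Fixture integrity is pinned by MD5 in the test suite.

## What the tests do and do not show

The synthetic phantom validates the *geometry*: rigid-motion invariance
(the central claim) to 1e-9° over the double-oblique poses and 1000 random
rigid motions, exact recovery of known torsions and angulations, mirror
consistency, and decoupling of the two angles. It does not validate
landmark *placement*: real CT measurement error is dominated by where
observers put the reference points on real, partly ambiguous anatomy, which
only the packaged repeated-measurement data speak to (CVs of 0.24–0.41% for
the reproducible targets). The Gaussian jitter model is isotropic and
independent across landmarks, which real placement error is not
(anatomical ambiguity is directional); the jitter results are order-of-
magnitude checks, not precision claims.

## Known limitations

- Sagittal-plane deformity (procurvatum/recurvatum) and translational
  deformity are out of scope; the method measures torsion and frontal-plane
  angulation only.
- The dorsal plane is oriented by the proximal retrocondylar axis. A
  configurable alternative reference (distal joint axis, or a bisector)
  would change the varus/valgus readout on bones with large torsion; the
  retrocondylar orientation is the fixed convention here.
- Mapping of left bones onto the shared readout convention is a package
  convention validated by internal mirror consistency; no external
  left-bone reference standard exists.
- Combined large deformities couple weakly (see above); readouts remain
  exact at the 0.1° reporting resolution for moderate deformity but the
  operators do not commute exactly.

## Problem sizes used in the suite

The property tests use 1000 random rigid motions, 1000 jitter replicates,
and 200+ random regression instances with n ≤ 12 — sizes chosen so each
property is exercised across its domain while the whole suite runs in
seconds.
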