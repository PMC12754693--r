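---
title: "Multi-bone shape modeling of foot morphology: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-bone shape modeling of foot morphology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, conventions and design decisions behind
footmorph: a pipeline for asking whether feet with chronic ankle
instability (CAI) differ skeletally from cavus (high-arch) and rectus
(neutral) feet, where those differences localise, and whether they are
inter-bone *alignment* or intrinsic bone *shape*.

## The anatomical frame

Every module shares one coordinate convention: **+X anterior, +Y superior,
+Z toward the right-lateral side**, floor plane Y = 0, units mm. The
sagittal projection drops Z; the coronal projection drops X. Left feet are
standardised by mirroring Z → −Z (with triangle winding flipped so
surfaces stay outward-oriented); `mirror_foot()` refuses right feet so a
foot can never be silently double-mirrored. Sign conventions are
side-invariant: the hindfoot angle measures lateral deviation as positive
on either side by flipping the lateral direction for left feet.

## The synthetic cohort generator

No patient scans ship with the package; instead the generator builds
schematic feet whose three radiographic angles are *exactly known*. Each
bone is a fixed-topology primitive (ellipsoid or box surface grid, roughly
150–300 vertices per bone) in a local frame; a deterministic kinematic
construction poses them:

1. **Calcaneal pitch (CI).** The calcaneus template carries two designed
   landmark clusters on its inferior surface at equal local height — a
   posterior plantar tuberosity and an anterior inferior process — so its
   inferior line is horizontal in the template. The bone is pitched about
   the mediolateral axis by a *pre-compensated* angle
   CI\* = atan(tan CI / cos HAA), so that after the later coronal tilt the
   sagittally projected inferior line measures exactly CI.
2. **First-ray pitch (MA).** The talus is pitched to a declination tied to
   the arch (−(5° + CI/2)); the forefoot chain (navicular, cuneiforms,
   cuboid, metatarsals) is pitched to the talar declination minus MA about
   a naviculocuneiform pivot. Meary's angle is the difference of the two
   sagittal axis elevations, so MA is planted exactly and positive MA means
   a plantarflexed first ray (the cavus, apex-dorsal sense).
3. **Hindfoot tilt (HAA).** The calcaneus is tilted about the
   anteroposterior axis by −HAA under a vertical tibia. Because both the
   tuberosity centroid and the bone centroid lie on the template midline
   (z = 0), the coronal projection of their connecting line measures
   exactly −HAA, independent of the sagittal pose.

The rotation order (CI, then MA, then HAA) plus the CI\* compensation makes
the construction an exact fixed point of the measurement operators: on
noiseless feet all three angles are recovered to numerical precision
(≈1e-14°, tested at 1e-6°) over the full study range
(MA −10°…35°, HAA 0°…19°, CI 9°…27°).

Per-subject variation enters as (a) iid Gaussian vertex noise applied in
each bone's **local template frame before posing** — so world-frame group
differences stay attributable to the planted angles — and (b) a log-normal
global scale jitter. One global seed fans out to per-subject substreams
(`seed + subject index`), so cohorts are reproducible and insensitive to
generation order.

Cohort defaults are the study conditions: group sizes 28 rectus / 29 cavus
/ 23 CAI; MA means 0.2 / 17 / 12° (SD 2.6 / 8.6 / 8.6), HAA means
9.8 / 5.9 / 6.0° (SD 3.4 / 4.1 / 3.9), CI means 19 / 21 / 22°
(SD 3.6 / 3.1 / 3.1); 46% left feet (the published pooled laterality; the
per-group split is not representable in a single-fraction parameter).
Angles are drawn from untruncated normals — published ranges hint at mild
truncation, which we do not model. Defaults for the free parameters were
chosen once: surface noise SD 0.3 mm (the scale of segmentation surface
error at sub-millimetre CT voxels) and scale jitter SD 0.05 (≈5% body-size
variation).

The bone count deserves a note: the source anatomy lists 13 names yet is
described as a 14-bone model; we include the fibula (standard in
weight-bearing ankle segmentations, paired with the tibia) as the 14th
bone. It participates in alignment and statistics but in no angle
measurement.

## Radiographic measurement

The measurement toolkit being emulated publishes no formulas, so the
operators here are explicit operational definitions validated against the
generator's ground truth rather than against an unpublished reference —
this is the package's central, deliberate substitution:

* **Longitudinal axes** are covariance principal axes with an
  anterior/superior orientation hint, not landmark pairs; a bone whose
  first-to-second eigenvalue ratio falls below 1.2 has no defined axis and
  errors ("near-spherical").
* **Extreme landmarks** (most plantar point of a calcaneal third, most
  plantar-posterior tuberosity point) are computed as the centroid of all
  vertices within a small band of the extreme (3 mm on height, 6 mm on the
  plantar-posterior score). On noiseless meshes the band captures exactly
  the designed landmark cluster, preserving exactness; under vertex noise
  it averages ~9 vertices, keeping angle errors well inside the 1° contract
  at 0.5 mm noise (worst case ≈0.85° over a 240-case grid).
* MA and CI are invariant to the coronal tilt and to mirroring; HAA is
  sign-stable under mirroring (left varus maps to right varus).

Foot-type classification follows the clinical rule with inclusive bounds:
rectus iff −4.5° ≤ MA ≤ 4.5°, cavus iff MA > 4.5°, otherwise "other".

## Correspondence and Procrustes frames

Cross-subject correspondence is **inherited from the shared template
topology**: particles are a fixed, deterministic subsample of template
vertex indices (uniform stride over a fixed permutation, 128 per bone by
default), so particle k is the same template vertex for every subject.
An entropy-based particle-optimisation stage is intentionally not
reimplemented — the statistics, not the optimiser, are the analysis target,
and template correspondence is exact where optimised correspondence is
approximate. For external meshes without shared topology this assumption
must be established upstream; the package validates equal per-bone vertex
counts and refuses otherwise.

Generalized Procrustes (whole foot, with scaling) produces the **world
frame**: configurations are centered, scaled to unit centroid size, then
iteratively rotated to the evolving mean until the mean moves < 1e-8 (cap
100 iterations, warning on non-convergence). The iteration starts from the
order-invariant raw average so the converged gauge does not depend on
subject ordering, and it also stops when the objective (sum of squared
distances to the mean) plateaus at relative 1e-12 — relevant because a
nearly axially-symmetric bone leaves one rotation direction weakly
identified and the mean can drift at numerically irrelevant magnitude.
Scaling is *not* part of ICP; size removal belongs to Procrustes only.

The **local frame** re-aligns each bone independently across subjects by
rigid-only Procrustes to the bone's cohort mean. Per-bone scaling is
deliberately not removed: whole-foot size is already gone, and removing
per-bone scale would delete relative-bone-size shape signal. World-frame
group differences therefore mean pose/alignment; local-frame differences
mean intrinsic shape (including relative size).

ICP (`icp_align`) uses single-direction nearest-neighbour correspondence
from source to target vertices with the closed-form SVD rigid solution,
tolerance 1e-6 mm, cap 100 iterations; its RMS trace is provably
non-increasing and is asserted in tests. The pipeline aligns every subject
to the first rectus subject in manifest order — the choice of reference is
a design decision (the source methods name none); pooled-cloud alignment
preserves inter-bone pose, which the alignment analysis needs.

## Statistics

* **PCA**: column-mean-centered SVD; at most n−1 modes; score variance
  equals the eigenvalue; percent variances sum to 100.
* **Parallel analysis** for retention: distribution-free permutation null
  (each column independently row-permuted), 1000 replicates, 95th
  percentile, retained = longest prefix of modes whose observed eigenvalue
  *strictly* exceeds the null percentile at the same rank (a tie is not
  retained). The null type, replicate count and percentile are explicit
  package choices; the source analysis does not state its own.
* **Normality**: one-sample KS against a normal with estimated mean/SD and
  the asymptotic p (matching the stated procedure); the statistically
  stricter Lilliefors correction is available behind a flag. Groups smaller
  than 5 record NA rather than aborting.
* **Per-mode group tests**: classical one-way ANOVA with Tukey–Kramer post
  hoc (studentized range, unequal-n standard errors) and η² = SS_b/SS_t
  with benchmark labels (0.01/0.06/0.14). All retained modes are tested
  without cross-mode multiplicity correction — matching the emulated
  procedure; this is a statistical caveat, not an oversight.
* **Radiographic group tests**: Welch ANOVA (weights nᵢ/sᵢ²,
  Welch–Satterthwaite df) with Games–Howell post hoc (per-pair Welch df,
  q = t√2) and Hedges g with the small-sample correction
  J = 1 − 3/(4N−9).
* **Particle maps**: two-sample Hotelling T² per particle in each frame;
  Benjamini–Hochberg FDR applied separately within each frame and each
  group pair (the source states only "FDR"; BH per frame per comparison is
  our explicit choice). Classification: world-only → alignment_only,
  local-only → shape_only, both → alignment_and_shape, neither → none.
  Particles with singular pooled covariance are logged, excluded from
  testing and classified none rather than aborting the map.

Every statistic is validated in the test suite against an independent
oracle: aov/TukeyHSD/oneway.test/t-test identities, a 4000-draw permutation
Hotelling p (agreement within 0.02), a hand-computed BH step-up, Tukey
family-wise error and Welch type-I calibration at 1000 simulated nulls
each, and BH false-discovery calibration at 500.

## What passing tests do and do not show

The generator emulates *exactly three degrees of anatomical freedom* plus
noise and size. Consequences to keep in mind when extrapolating to real
cohorts:

* Mode 1 of a synthetic cohort carries ~95% of variance, because planted
  angle variation dominates iid vertex noise; real feet spread their
  variance over many anatomical modes, with the leading mode typically far
  below that. The pipeline-level recovery claim is therefore qualitative:
  mode 1 separates rectus from cavus with a large effect (η² ≥ 0.14,
  p < 0.05 in ≥ 90% of seeds), and the CAI-vs-cavus particle-difference
  percentage is the smallest of the three comparisons.
* Whole-foot scaling interacts with pose: a plantarflexed forefoot changes
  the foot's centroid size, so after size removal bones differ slightly in
  scale between groups, and with n = 80 the local frame can flag this as
  "shape". On synthetic cohorts alignment_and_shape percentages are
  therefore upper bounds on what pure pose differences would produce;
  shape_only stays near zero, which is the diagnostic that matters.
* Statistical calibration (type-I error, FDR) is checked under the
  generator's normal model; heavy-tailed real-world deviations are not
  exercised.

## Problem sizes and numerics

Test and acceptance runs use deliberately desk-scale sizes chosen as
package defaults: 8–32 particles per bone and 100–200 permutation
replicates in test pipelines (against 128 and 1000 in the analysis
defaults), cohorts of 20–80 feet, calibration suites at 500–1000
replicates, and a 240-case angle-recovery grid. A full default pipeline
(80 subjects, 128 particles/bone, 1000 permutations, ICP on) completes in
a few minutes on one CPU.

Numerical conventions collected in one place: GPA tolerance 1e-8 (mean
change) with objective-plateau stop at relative 1e-12; ICP tolerance
1e-6 mm; axis-elongation threshold 1.2; landmark bands 3 mm (plantar
height) and 6 mm (plantar-posterior score); parallel-analysis ties not
retained; BH at α = 0.05; degenerate inputs (zero-area faces, collinear
point sets, zero-variance samples, singular covariances) raise distinct
errors rather than propagating NaN, except singular per-particle
covariances inside a map, which degrade gracefully as described.

## Known limitations

* Schematic anatomy: no articular surfaces, no cortical detail; mirroring
  and ICP behave as on real meshes, but mesh-quality pathologies
  (holes, flipped patches) are out of scope.
* Correspondence for external real meshes requires shared topology; no
  surface-based particle optimisation is provided.
* Binary STL is inherently float32; its round trip is single-precision
  (binary PLY and all ASCII formats round-trip at double precision).
* The radiographic operators are operational definitions; absolute
  agreement with any particular clinical toolkit is not claimed, only
  exact recovery of the construction they define and robustness to noise
  and reframing.
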