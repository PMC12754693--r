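# footmorph

Statistical shape modeling of the 14-bone foot and ankle complex, built for
studying how skeletal morphology differs between chronic ankle instability
(CAI), cavus and rectus (neutral) foot types.

Chronic ankle instability has long been suspected to have a structural,
bony component: a high medial arch and a varus hindfoot load the lateral
column and predispose to recurrent sprains. Weight-bearing CT makes the
loaded 3D skeleton measurable, and multi-bone statistical shape models
(SSM) can localise where CAI feet differ from cavus and neutral feet —
and whether those differences are intrinsic bone *shape* or inter-bone
*alignment*. This package reimplements that analysis chain as reusable,
tested R code, with a parametric synthetic cohort generator in place of
patient scans so that every stage is verifiable against known ground truth.

## What it does

* **Synthetic cohorts** — `build_parametric_foot()` constructs a schematic
  14-bone foot (calcaneus, cuboid, three cuneiforms, fibula, metatarsals
  1–5, navicular, talus, tibia) whose three radiographic angles are planted
  *exactly* by a deterministic kinematic construction; `sample_cohort()`
  draws group-structured cohorts (28 rectus / 29 cavus / 23 CAI by default,
  with per-group angle means and SDs matching the published study
  conditions, 46% left feet, surface noise and scale jitter).
* **Radiographic measurement** — `meary_angle()` (MA: sagittal angle
  between talar and first-metatarsal axes; positive = first ray
  plantarflexed, the cavus sense), `hindfoot_alignment_angle()` (HAA:
  coronal angle between the tibial axis and the calcaneal hindfoot axis;
  valgus positive), `calcaneal_inclination()` (CI: pitch of the inferior
  calcaneal line), and the clinical rule `classify_foot_type()` (rectus for
  −4.5° ≤ MA ≤ 4.5°, cavus above).
* **Mesh handling** — PLY/STL/OBJ read/write, left-to-right mirroring with
  winding repair, principal axes, and iterative-closest-point rigid
  alignment (`icp_align()`).
* **Correspondence and Procrustes** — fixed-template correspondence
  particles (`extract_particles()`), generalized Procrustes with scaling
  for the *world* frame (`generalized_procrustes()`), rigid per-bone
  alignment for the *local* shape frame (`per_bone_local_frames()`).
* **Shape statistics** — PCA (`pca_fit()`), permutation-based parallel
  analysis for mode retention (`parallel_analysis()`), per-mode
  Kolmogorov–Smirnov normality, one-way ANOVA with Tukey post hoc and η²,
  Welch ANOVA with Games–Howell and Hedges g for the radiographic
  measures, and per-particle two-sample Hotelling T² maps with
  Benjamini–Hochberg FDR that classify each correspondence particle as
  `alignment_only`, `shape_only`, `alignment_and_shape` or `none`
  (`particle_significance_map()`).
* **Pipeline** — `run_pipeline()` orchestrates
  generate/ingest → mirror → measure → ICP → particles → GPA → PCA →
  statistics → particle maps, with config validation, content-addressed
  stage caching and a machine-readable JSON report. A thin CLI wrapper
  lives in `inst/cli/run_analysis.R`.

The central statistic, per particle and frame, is Hotelling's two-sample
T² = (n_a n_b)/(n_a+n_b) · d′ S⁻¹ d with d the 3D mean particle
difference and S the pooled covariance, referred to
F(p, n_a+n_b−p−1); a particle significant in the world frame but not the
local frame reflects alignment (pose) differences, local-frame
significance reflects intrinsic bone shape.

## Worked example

```r
library(footmorph)

foot <- build_parametric_foot(ma = 17, haa = 5.9, ci = 21,
                              noise_sd = 0.3, seed = 42)
angle_measures(foot)
#>         ma      haa       ci foot_type
#> 1 17.23797 6.115761 20.85539     cavus

cfg <- validate_config(list(generator = list(group_sizes = c(10, 10, 8)),
                            particle_count = 32L, n_permutations = 200L,
                            seed = 7))
report <- run_pipeline(cfg, quiet = TRUE)
print(report)
#> <analysis_report> 28 subjects; 1 retained modes; mode 1 explains 95.8% variance
#>   mode percent_variance    f        p eta_sq eta_label min_ks_p
#> 1    1             95.8 13.6 0.000102   0.52     large    0.881
#>   CAI_vs_rectus: 15.6% alignment only, 0.0% shape only, 0.00% both
#>   cavus_vs_rectus: 78.1% alignment only, 0.2% shape only, 20.09% both
#>   CAI_vs_cavus: 0.0% alignment only, 0.0% shape only, 0.00% both
```

Reading the output: the foot measured 17.2° MA against a planted 17°
(surface noise accounts for the difference; noiseless feet recover planted
angles to 1e-6°). In the 28-subject cohort, PCA mode 1 — dominated by the
planted arch/first-ray variation — separates the groups (ANOVA
p ≈ 1e-4, η² = 0.52, large) and the particle maps localise cavus-vs-rectus
differences as predominantly alignment rather than intrinsic bone shape,
while CAI vs cavus shows essentially no particle-level differences — the
qualitative signature of CAI feet carrying cavus-like morphology.

## Scope notes

Synthetic feet are schematic primitives, not anatomical reconstructions:
the generator plants three clinically defined angles exactly and adds
vertex-level noise, which is what the measurement and statistics layers
need for validation. Shape variation beyond those angles (and hence
realistic mode spectra) is deliberately out of scope; see the methods
vignette (`vignettes/foot-shape-modeling.Rmd`) for the model, assumptions
and limitations.
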