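---
title: "Quality assessment of structural T1 MRI: models, features and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality assessment of structural T1 MRI: models, features and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t1qc)
```

## The problem and the model

High-resolution T1-weighted brain volumes acquired with spoiled-gradient
sequences suffer from a small set of recurring artifacts: rippling behind
the orbits caused by eye movement during the long acquisition, broad
wave-like replicas of the bright skull fat near the vertex caused by head
motion ("ringing"), and wrap-around aliasing when the coronal field of
view is smaller than the head, folding the nose onto the posterior brain.
Each of these is a *ghost*: displaced, attenuated copies of a bright
moving (or out-of-field) structure along the phase-encode direction.

`t1qc` treats quality assessment as supervised classification. A volume
is represented by a feature vector with two groups of entries:

* **Volumetric features** summarize global contrast. `VF1` is the
  100-bin histogram of the intensity volume over `[0, I_max]`; `VF2_c`
  the 100-bin histogram of the tissue probability map of class
  c ∈ {GM, WM, CSF} over the fixed domain `[0, 1]`; and `VF3` the
  gray/white contrast score
  `gw_t_score = (μ_WM − μ_GM) / sqrt(σ²_GM + σ²_WM)` computed from the
  intensity distributions inside the 0.5-thresholded GM and WM masks.
  Usable volumes have well-separated gray and white profiles; artifacts
  blur them.

* **Artifact-specific features** read ghost energy out of air regions
  where no anatomy belongs. The *background-mask* is built by spatially
  normalizing every subject's background probability map, averaging
  across the cohort, transforming the average back into each native
  space and thresholding at 0.5. The *eye-mask* restricts it to
  background directly anterior of the eye sockets; the *ring-mask* to an
  axial slab near the top of the head. `ASF1` sums the per-column median
  of non-zero background intensities in the eye-mask and takes the
  maximum over axial slices; `ASF2` does the same for the windowed
  absolute difference `|nv(x+20) − nv(x)|/20` in the ring-mask, which
  responds to wave-like structure but not to a flat noise floor; `ASF3`
  sums each mid-sagittal slice along z and takes the maximum over slices
  of the minimum over y — any clear air plane behind the head floors the
  statistic, while an overlaid wrapped nose removes all such planes.

The classifier is an RBF-kernel SVM evaluated by a balanced, repeated,
cross-validated protocol (below). Sensitivity is the percentage of
not-usable volumes correctly flagged, specificity the percentage of
usable volumes correctly passed.

## Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `background_threshold` | 0.5 | probability | closed comparison (`>= 0.5`), so the boundary case is deterministic |
| `ring_lower_frac` | 0.6 | fraction of head z-extent | keeps eye-movement ghosts out of the ring slab |
| `ring_top_margin` | 5 | axial slices | avoids axial wrap-around at the vertex |
| `asf_window` | 20 | voxels | differencing distance for `ASF2`; with 124 sagittal slices the difference vector has 104 entries |
| `asf_half_width` | 15 | slices | `ASF3` scans `2 × 15 = 30` sagittal slices |
| `asf_midline` | `"auto"` | index | `round(nx / 2)`; a dataset-specific midline (e.g. 62 on a 124-slice acquisition) can be configured |
| `n_folds` | 10 | — | 90% train / 10% test |
| `n_repeats` | 1000 | — | balanced-subsample repeats |
| `n_permutations` | 10000 | — | label permutations for the null |
| `cost`, `gamma` | 1, `"median"` | — | SVM regularization and kernel width |

The ring-slab bounds exist to isolate the ringing signal but have no
published values; both are exposed in the configuration. The eye-socket
boxes shipped by `default_eye_boxes()` match the phantom geometry only —
for scanner data they must be estimated once on the normalization
template and supplied via `qc_config()` or the YAML configuration.

The SVM kernel and hyperparameters are genuinely open design choices: we
default to a radial-basis kernel (quality classes are not linearly
separable in feature space), regularization constant 1, and a kernel
width set by the median-distance heuristic on the standardized training
fold. Features are standardized with training-fold statistics only, so
no information leaks from test folds; histogram counts and ASFs live on
very different scales, making standardization necessary.

## The evaluation protocol

Cohorts are imbalanced (most volumes are usable), so each repeat first
draws a balanced subsample: all minority-class volumes plus an equal-size
random draw of the majority class. The subsample is split into 10
stratified folds; per fold an SVM is trained on 90% and predicts the
held-out 10%; fold predictions are pooled into per-repeat rates. On a
balanced subsample, pooled accuracy is exactly the mean of sensitivity
and specificity — a property the test suite asserts. Repeats re-randomize
both the subsample and the fold assignment. Degenerate repeats (a
training fold with one class) are redrawn with a warning so the repeat
count stays interpretable.

The permutation null repeats the identical machinery with training
labels shuffled within each fold (test labels intact), and the p-value
uses the add-one estimator `(1 + #{null ≥ observed}) / (1 + N)`, which
cannot return zero from finitely many permutations. Pairwise comparisons
between feature combinations and between severity groups use Student's
two-tailed t-test (equal-variance form), flagged at p < 0.05 (`*`) and
p < 10⁻³ (`**`); an unadjusted and a Bonferroni-adjusted p-value are both
reported.

## The phantom generator

`generate_head_phantom()` builds an ellipsoidal head — skull and
subcutaneous-fat shell, gray-matter shell, white-matter core, two CSF
ventricles — plus two anterior eye globes and a nose wedge running from
the face to the anterior edge of the grid (so a too-small field of view
has anatomy to fold). Mean intensities are ordered
background ≪ CSF < GM < WM ≤ skull/fat; additive Gaussian noise
(default SD 2 on a WM mean of 100) is clamped at zero. Ground-truth
tissue maps are the one-hot class partition mixed toward uniform by a
small softening weight, so probabilities are in (0, 1) and sum exactly
to one at every voxel. Phantoms are born in normalized space with an
identity transform pair.

Artifact injectors are image-space idealizations, not k-space
simulations: the features under test measure background signal, and
image-space replicas have analytically checkable support.

* *Eye movement*: attenuated copies of the eye-globe signal shifted
  anteriorly along y, with per-replica jitter; injected energy is
  proportional to the amplitude.
* *Ringing*: attenuated copies of the bright skull/fat rim of the upper
  third of the head shifted laterally along x.
* *Aliasing*: the anterior-most `ceiling(amp · ny · 0.2)` coronal planes
  of the nose's axial band fold over the posterior edge, scaled by the
  amplitude so injected energy grows continuously with severity. With
  `overlay = FALSE` the folded planes sit at the very posterior edge,
  leaving a pure-background gap behind the head (the separable
  scenario); with `overlay = TRUE` they tile the region from the back of
  the head to the posterior edge, emulating the tight field of view in
  which wrapped anatomy lands on the brain and no clear air plane
  survives — the scenario `ASF3` is built to catch. A plain shifted
  block would always leave empty planes behind it and make the two
  scenarios indistinguishable to a full-range minimum; the tiling is
  what reproduces the three-scenario behaviour (no aliasing ≈ gap ≪
  overlay). Only the nose's axial band is folded: wrapping the whole
  noise field would leak wrap noise into the ring slab and couple the
  aliasing amplitude to `ASF2`.

Every injector is the exact identity at amplitude zero, and all
randomness is seed-derived, so cohorts are bit-reproducible.

`generate_cohort()` labels subjects by construction: usable subjects
draw all three amplitudes uniformly below 0.45, so — like visually
accepted borderline scans — they may carry slight-to-moderate artifacts;
not-usable subjects have one or two amplitudes above 0.55. Severity
grades follow fixed amplitude cutpoints (none < 0.1 ≤ slight < 0.35 ≤
moderate < 0.65 ≤ heavy); only their ordering matters. Per-subject
tissue contrast (CSF/GM/WM means drawn from U(35,45), U(62,78),
U(92,108)) and map softness (U(0.02, 0.08)) are jittered so that global
histogram features vary between subjects for reasons unrelated to
artifact load, as they do across real scanners and brains. An early
all-or-nothing amplitude scheme made the cohort separable by any
feature set; the borderline band restores the qualitative structure in
which artifact-specific features outperform global histogram features.

**What the phantom does not emulate**: real anatomy and its variability,
bias fields, Rician noise statistics, k-space-accurate ghosting, coil
sensitivities, or segmentation failure modes. Passing tests on phantoms
therefore demonstrate the correctness and selectivity of the feature
computations and the soundness of the evaluation machinery — not
clinical-grade performance on scanner data, which requires labelled real
volumes.

## Numerical choices and degenerate inputs

* Histogram bins are `((n−1)Δ, nΔ]` with the first bin closed at zero,
  so exact zeros (air) are counted and counts always sum to the voxel
  total; bin edges are computed as `domain_max · (0:100)/100` to keep
  edge cases (e.g. a constant 0.5 map → bin 50) exact in floating point.
* `VF2` keeps `domain_max = 1` even when the observed map maximum is
  lower.
* The `gw_t_score` denominator uses the masked non-zero intensities;
  masked zeros are mask artifacts, not tissue. An all-constant class
  raises a zero-variance error rather than returning infinity. The
  "literal" mode, which averages histogram bin counts instead of
  intensities, is retained because that reading makes the mean
  difference a voxel-count difference, independent of contrast — the
  discrepancy is asserted in the tests.
* Median of an empty column in the noise vector is 0 (the neutral
  element of the downstream sum); even-count medians are midpoints.
* Slices where the eye/ring mask is empty are skipped in the maxima —
  equivalent to contributing zero, but cheaper.
* `ASF3`'s minimum runs over the full coronal range (not a posterior
  crop): the posterior region motivates the feature, but the full-range
  minimum is what makes the gap scenario floor the statistic.
* Mask warping uses nearest-neighbour interpolation (preserves
  booleanness); probability-map warping is trilinear with clamping to
  `[0, 1]`. The identity transform short-circuits to a copy.
* Negative intensities on file read are clamped to zero with a warning
  (interpolation overshoots); volumes failing to load raise distinct,
  named error conditions (`missing_file`, `non3d`,
  `unreadable_header`).
* The intensity-only background fallback (`estimate_background_map`)
  thresholds with Otsu's method, applies one binary closing, and
  flood-fills air from the grid border so interior cavities stay part of
  the head. It assumes head-brighter-than-air contrast and warns
  otherwise.
* Seeds: every stochastic routine takes an integer seed and restores the
  caller's RNG state; repeat/permutation seeds are derived from the
  master seed and stay within 32-bit range.

## Problem sizes used in the shipped checks

The default phantom grid is 124×128×128 (mirroring a 124-slice sagittal
acquisition, under which the ASF2 difference vector has the canonical
104 entries). The test suite and the acceptance script run the same code
on reduced grids — 40×48×48 phantoms, 48×56×56 cohort subjects, cohorts
of 100–120 subjects, 60–100 protocol repeats and 100 permutations —
sizes chosen so the full pipeline, from cohort generation to permutation
null, reruns from scratch in minutes on a laptop-class machine while
leaving every statistical check comfortably powered.

## Known limitations

* Only affine native↔normalized transforms are supported; deformation
  fields are out of scope.
* Ringing that stays entirely inside the brain leaves the background
  untouched and is invisible to `ASF2` by construction.
* `ASF3` targets coronal wrap; axial or sagittal aliasing would need the
  analogous statistic along the other axes (the machinery generalizes,
  but it is not wired up).
* Grainy images, head-movement streaking and teeth-filling artifacts
  have no dedicated features; volumes where only those occur are
  classified on the volumetric features alone.
* The label data model records the color/severity/vote vocabulary of
  two-stage visual inspection, but the package does not attempt to model
  rater behaviour.
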