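# t1qc — automated quality assessment of T1-weighted structural brain MRI

Structural 3D T1-weighted brain volumes are routinely screened by eye
before morphometric analysis, because acquisition artifacts — rippling
behind the orbits from eye movement, broad wave-like ghosting of the
bright skull fat near the top of the head ("ringing"), and wrap-around
aliasing that folds the nose onto the back of the brain — corrupt tissue
segmentation and downstream statistics. Visual inspection is slow and
subjective. `t1qc` automates it: it extracts image-quality features from
each volume and classifies the volume as **usable** or **not-usable**
with a support vector machine evaluated under a balanced, repeated,
cross-validated protocol.

The package is aimed at neuroimaging labs curating large T1 databases,
and at methodologists who want a fully synthetic, ground-truth test bed
for artifact-detection features: a parametric head-phantom generator
injects each artifact at controlled amplitude, so every stage of the
pipeline is testable without scanner data.

## Features

Let `I(x, y, z)` be the intensity volume (x sagittal, y coronal
anterior→posterior, z axial) and `p_c` the tissue probability maps
(GM, WM, CSF, skull, fat, background) from unified segmentation.

**Volumetric features**

- `VF1` — 100-bin histogram of `I` over `[0, I_max]`, bin width
  `I_max / 100`.
- `VF2_c` — 100-bin histogram of `p_c` over the fixed domain `[0, 1]`,
  for c ∈ {GM, WM, CSF}.
- `VF3 = gw_t_score = (μ_WM − μ_GM) / sqrt(σ²_GM + σ²_WM)`, the contrast
  between the masked (`p_c ≥ 0.5`) gray- and white-matter intensity
  distributions.

**Artifact-specific features**, measured in masks built from the
group-averaged, back-transformed background probability map thresholded
at 0.5 (air entirely outside the head):

- `ASF1` (eye movement) — in the *eye-mask* (background directly anterior
  of the eye sockets), per axial slice the noise vector
  `nv(x) = med_y { I(x, y, z0) > 0 }`; `ASF1 = max_z0 Σ_x nv(x)`.
- `ASF2` (ringing) — in the *ring-mask* (background slab near the top of
  the head), the windowed difference
  `nvd(x) = |nv(x + 20) − nv(x)| / 20`; `ASF2 = max_z1 Σ_x nvd(x)`.
- `ASF3` (aliasing) — over 30 sagittal slices centered on the midline,
  the raw vector `rv(y) = Σ_z I(x1, y, z)`;
  `ASF3 = max_x1 min_y rv(y)`. A clear air plane behind the head keeps
  `ASF3` at the noise floor; a wrapped nose overlaid on the head removes
  every such plane and raises it toward tissue intensity.

**Evaluation protocol** — per repeat: draw a class-balanced subsample,
split it into 10 stratified folds, standardize features on the training
portion only, train an RBF-kernel SVM, pool the fold predictions into
accuracy, sensitivity (% of not-usable correctly flagged) and
specificity (% of usable correctly passed). A permutation variant
shuffles training labels to establish the chance level, and Student's
two-tailed t-tests compare feature combinations and severity groups.

## Worked example

```r
library(t1qc)

## a clean phantom vs. one with heavy eye movement + ringing
ph <- generate_head_phantom(phantom_spec(shape = c(48, 56, 56), seed = 7))
extract_features(ph$volume, ph$maps, ph$transform, subject_id = "clean")
#> <feature_vector> clean: vf3 = 10.6, asf1 = 39.1, asf2 = 0.691, asf3 = 36.7

bad <- inject_ringing(inject_eye_movement(ph$volume, ph$maps, 0.8, seed = 7),
                      ph$maps, 0.8, seed = 7)
extract_features(bad, ph$maps, ph$transform, subject_id = "ghosted")
#> <feature_vector> ghosted: vf3 = 1.23, asf1 = 419, asf2 = 2.5, asf3 = 36.9
```

`asf1` jumps from the noise floor (39) to 419 under eye-movement
ghosting and `asf2` from 0.69 to 2.5 under ringing, while `asf3`
(aliasing) is untouched; the gray/white contrast score `vf3` collapses
from 10.6 to 1.2 as ghost energy inflates the within-tissue variance.

```r
## a labelled synthetic cohort, end to end
co  <- generate_cohort(40, usable_fraction = 0.5, seed = 1)
ft  <- cohort_features(co)
train_and_evaluate(ft, ft$final,
                   experiment_config(c("ASF1", "ASF2", "ASF3"),
                                     n_repeats = 50, seed = 1))
#> <evaluation_result> 50 repeats
#>   accuracy    93.5% (SE 0.18)
#>   sensitivity 87.1% (SE 0.35)
#>   specificity 100.0% (SE 0.00)
```

A command-line front end with `simulate`, `extract` and `classify`
subcommands is installed at `inst/cli/t1qc`.

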