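---
title: "Automated lymphoma segmentation and quantification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated lymphoma segmentation and quantification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`lymphseg` automates a workflow that is otherwise a major bottleneck in
quantitative FDG-PET studies of lymphoma: identifying every avid lesion in a
whole-body PET/CT scan, segmenting it, and reducing the segmentation to the
handful of patient-level metrics with prognostic value. This vignette explains
the models the package implements, the choices that were genuinely open and how
they were resolved, and what the synthetic phantom experiments do and do not
demonstrate.

## The reference segmentation model

Clinical reference masks in this workflow are not drawn freehand. A reader
places loose template regions of interest (ROIs) around disease and a
deterministic rule selects the lesion voxels inside each region:

* a fixed threshold, `SUV > 2.5` (strict inequality), and
* a relative threshold, `SUV >= 0.40 * SUVmax` of that region (non-strict, so
  the maximum voxel itself is always selected),

with the final mask being the **union** of the two selections, followed by
removal of 1-voxel islands. The union matters: next to a bright lesion, the
40% rule alone would erase any small lesion dimmer than 40% of the regional
maximum, and the fixed floor rescues it. `threshold_union()`,
`remove_islands()` and `build_reference()` implement exactly this. Two
interpretation points were unspecified and are resolved as follows:

* the 40% rule uses the **per-region** SUV maximum (the only scope consistent
  with the rescue rationale above);
* island removal runs once on the merged mask across all regions, with
  26-connectivity (the most permissive 3D adjacency, standard in lesion
  analysis and used for every component operation in the package).

## The network

The segmentation model is a 3D, patch-based, multi-resolution-pathway
convolutional network of the DeepMedic family. Each pathway applies eight
*valid* (unpadded) 3×3×3 convolutions, so a 25³ input patch yields a 9³
output tile. The full-scale configuration uses three pathways — full
resolution plus two that see the image average-pooled by factors 3 and 5,
widening the receptive field by the same factor — with 90, 90, 110, 110, 110,
110, 130 and 130 convolutional features, two 250-feature fully connected
layers implemented as 1×1×1 convolutions, and a 2-class softmax per voxel.
Inputs are two channels, PET and CT, both z-scored inside the body mask.
Downsampled pathway outputs are upsampled by nearest-neighbour repetition and
cropped to the normal pathway's tile; the downsampled input segments are sized
so the feature maps match the normal tile before concatenation.

Implementation notes that matter for reproducibility:

* Pooling for the downsampled pathways is anchored at voxel 0 of the global
  grid rather than at each patch center. Training patches and dense-inference
  tiles therefore read identical values for identical voxels, which makes
  tiled inference exactly consistent with single-pass inference (verified in
  the test suite to float tolerance).
* Dense inference assembles non-overlapping output tiles; borders are handled
  by edge-padding the input context, never by shrinking the output. Voxels
  outside the body mask are assigned probability 0.
* Convolution arithmetic runs in single precision via an im2col + BLAS
  matrix-multiply kernel; everything else is double precision.

Training hyper-parameters are not dictated by the architecture and are exposed
in `deepmedic_config()`: voxelwise cross-entropy, Adam with learning rate
1e-3, minibatches of 10 patches, and class-balanced sampling (50% of patches
centred on a lesion voxel, 50% on a body voxel outside the reference —
restricting negatives to the body avoids spending capacity on air). No batch
normalization, dropout or augmentation is used by default. When validation
cases are supplied, the model checkpoints at the epoch with the lowest
validation loss; the nested train:validation split in `run_pipeline()`
defaults to roughly 7:1.

## Post-processing

`postprocess_ensemble()` applies, in fixed order: binarization at the
probability cut point (default 0.5); the same SUV threshold-union rule applied
within each connected component of each member's mask (aligning network
contours with the reference protocol's boundary definition); voxelwise
intersection of the member masks; and bone exclusion. Intersection is the
false-positive mechanism: a spurious detection survives only if every member
makes it, so the final mask is provably a subset of each refined member mask
and its false-positive count never exceeds the best member's.

Bone exclusion removes components dominated by CT values above 150 HU. The
strict reading — delete any component containing a single bone voxel — would
also delete true nodal disease abutting a vertebra, so the package removes a
component when more than `bone_fraction` (default 0.5) of its voxels are bone;
`bone_fraction = 0` restores the strict reading. Exclusion acts on the mask
itself so that every downstream feature is computed from the same object.

## The five metrics

From a binary mask and the SUV volume, `extract_features()` computes SUVmax
(g/ml), metabolic tumor volume MTV (cm³ = voxel count × voxel volume), total
lesion glycolysis TLG (= mean SUV × MTV, in g), the surface-area-to-volume
ratio SA/MTV (cm⁻¹), and the dissemination metric Dmax (cm), the distance
between the two lesions farthest apart. Conventions:

* Surface area counts exposed voxel faces (6-neighbourhood) times face area.
  This is exact, additive and trivially checkable against enumeration, at the
  cost of overestimating a smooth surface by up to ~1.5×; a definition based
  on meshing would be smoother but is neither unique nor oracle-friendly.
* Dmax uses lesion centroids (mean of voxel centers, world coordinates),
  26-connected components, and is 0 when fewer than two lesions exist.
* Degenerate masks are flagged rather than silently zeroed: SUVmax and SA/MTV
  are `NA` for an empty mask.

## Evaluation protocol

Segmentations are scored voxelwise (Dice, sensitivity, positive predictive
value), optionally as a function of the probability cut point
(`threshold_sweep()`). Feature agreement uses Pearson correlation and relative
percent difference `100 * (auto - ref) / ref`, summarized by median and IQR;
quartiles use linear interpolation between order statistics (R type 7), the
common default, documented because several conventions exist. SUVmax
additionally reports exact matches (relative tolerance 1e-6), since agreement
there means the same voxel was selected by both masks. Subgroup analyses
dichotomize the cohort at the median of a disease characteristic (ties to the
low group) and compare DSC and |MTV RPD| between groups with two-sided
Wilcoxon rank-sum tests — exact when both groups have at most 25 cases and no
ties, otherwise the normal approximation with continuity and tie corrections.

## The phantom generator

`generate_phantom()` emulates the phenomenology this pipeline must cope with,
not the physics of PET acquisition. A soft-tissue (40 HU) ellipsoidal body in
air contains: axis-aligned ellipsoidal lesions with uniform uptake drawn from
SUV 3–15 on a low background (SUV 0.5–1.5); small benign hot structures (SUV
2.5–8) standing in for salivary glands, tonsils and ureters — the dominant
false-positive sites for this method on real scans; and bone ellipsoids at
400 HU. The PET is degraded by an isotropic Gaussian point-spread function
(FWHM 6 mm, representative of the relevant scanner generation) and additive
Gaussian noise (σ = 0.2 SUV; post-reconstruction noise is approximately
Gaussian, and this keeps the generator simple and exactly seedable, unlike a
sinogram-level Poisson model). Template ROIs are dilated bounding boxes around
lesions, with overlapping boxes merged — mimicking a reader's loose regions.
Benign structures are placed outside the template ROIs, as a reader excludes
normal physiology when placing them. Lesions are never planted in bone.

The truth bookkeeping records per-lesion voxelized volumes and the feature set
computed from the merged planted mask on the pre-blur PET, so planted MTV
equals extracted MTV exactly and every feature has an analytic-side oracle.

What the phantoms do **not** emulate: anatomy (no organs, no uptake
gradients), respiratory motion, scanner harmonization differences, or reader
variability. Lesions are single axis-aligned ellipsoids by default because
their voxelized volumes have simple analytic oracles; lobulated shapes
(unions of overlapping ellipsoids) are available via
`phantom_config(irregular_lesions = TRUE)`. Passing phantom experiments
therefore demonstrates the pipeline's internal correctness and its ability to
learn intensity-plus-context discrimination under blur and noise — not
clinical-grade performance on patient scans.

## Numerical and scale choices

* Resampling: output size `ceil(extent / target)` per axis, same world
  origin, linear interpolation with edge-value extension (nearest neighbour
  for labels, which must stay integer). Oblique NIfTI affines are rejected
  rather than silently reoriented.
* "Inside the patient" for normalization is a CT body mask: largest
  26-connected component above −500 HU (excluding air, keeping lung), with
  3D hole filling; PET and CT are normalized independently against it, with
  population variance. The CT copy fed to the network is clipped to
  ±1000 HU to bound implant outliers; the unclipped HU volume is always used
  for bone exclusion.
* Cross-validation: standard k-fold with near-equal fold sizes; the nested
  7:1 train:validation split provides the checkpoint criterion
  (best-validation-loss, a pragmatic choice where no criterion is canonical).
* Scaled-down experiments in the test suite and acceptance script use a
  compact configuration (2 pathways, features 8,8,12,12,12,12,16,16, fc 32)
  trained for 12 epochs of 5 batches × 10 patches on cohorts of 15–25
  phantoms of 64³ voxels at 2 mm — sizes chosen so the whole suite runs on a
  single CPU in minutes while still exercising every stage, including
  learning. The noiseless-recovery experiment draws lesion uptake from SUV
  4–15 so the per-region 40% cut (≥ 1.6) provably clears the 0.5–1.5
  background, which is the stated condition under which threshold recovery is
  an exact identity.

## Known limitations

* The exposed-face surface area inflates SA/MTV relative to mesh-based
  definitions; comparisons across packages should use one convention.
* Benign hot structures are learnable confusers only through size and
  context; with the compact network and short schedules some survive as false
  positives, exactly as salivary glands and tonsils do for the full-scale
  method on patient data.
* The learner is CPU-bound R/BLAS; it reproduces the architecture faithfully
  but is not intended for full-scale (90–130 feature, three-pathway, large
  cohort) training, which is a GPU workload.
* Only axis-aligned, positively oriented NIfTI grids are supported.
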