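---
title: "Methods: phantom-based radiomics, harmonisation and benchmarking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom-based radiomics, harmonisation and benchmarking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`liporad` implements a benign-versus-malignant lipomatous-tumour MRI
workflow: 3D radiomic feature extraction, empirical-Bayes batch
harmonisation, multi-classifier benchmarking under patient-grouped
cross-validation, and a small convolutional-network baseline, all
exercisable on a synthetic phantom cohort. This vignette records the
methods, the parameter choices and their rationale, the numerical
conventions, and the limits of what the phantom experiments demonstrate.

## The radiomic feature model

Each case is an image volume plus a binary lesion mask. Volumes are first
resampled to an isotropic grid (default 1 mm) by nearest-neighbour
interpolation for both image and mask; nearest-neighbour is deliberate for
the texture arm — it does not mix voxel intensities — and a linear option
(`interp = "linear"`) is exposed for sensitivity analysis. No intensity
normalisation or filtering is applied before feature extraction; shape and
histogram features consume the raw resampled data.

The 92-feature catalog is fixed and ordered (`feature_catalog()`):

* **Shape (14)** — voxel count, physical volume, mesh surface area,
  surface-to-volume ratio, sphericity, two compactness variants, spherical
  disproportion, maximum 3D diameter, three principal-axis lengths,
  elongation, flatness. Surface area comes from a marching-tetrahedra mesh
  at iso-level 0.5 on a lightly smoothed (Gaussian, σ = 0.7 voxels) copy of
  the mask with linear edge interpolation; smoothing removes the
  voxelisation staircase that otherwise biases the area upward by ~25%
  (a digital sphere of radius 20 then scores sphericity ≈ 0.98). The
  maximum diameter is exact over boundary-voxel pairs up to 5000 boundary
  voxels, beyond which extreme points over 200 random projections are used.
  Axis lengths are 4√λ from the eigenvalues of the voxel-coordinate
  covariance.
* **Histogram (14)** — population moments (kurtosis reported as excess),
  order statistics, interquartile range, energy, plus entropy and
  uniformity from a 256-equal-width-bin histogram over the observed range.
* **Texture matrices (21 + 13 + 13 + 5)** — intensities inside the mask
  are discretised by equal-probability quantization: thresholds sit at the
  k/N~g~ empirical quantiles (type-1, i.e. the smallest observed value
  whose empirical CDF reaches k/N~g~; ties map to the lower level), so
  occupancies are equal up to ties — with all-distinct values the
  max–min occupancy is ≤ 1. Quantization depends only on intensity ranks,
  making every downstream texture feature invariant to monotone intensity
  transforms such as scanner gain. Matrices are built at
  N~g~ ∈ {8, 16, 24, 32, 40, 48, 64}: GLCM and GLRLM slice-wise along the
  four classic in-plane directions at offset 1 voxel with counts pooled
  over slices (the four named angles are inherently 2D; pooling rather
  than per-slice feature averaging was chosen and is noted for sensitivity
  analysis), GLSZM and NGTDM fully in 3D with 26-connectivity. GLCMs are
  symmetrised before normalisation so correlation-type features are well
  defined. Feature values are averaged — mean over directions, then mean
  over N~g~ — giving one value per feature, which is the only aggregation
  consistent with a fixed-length feature vector across seven
  discretisations.
* **Gabor (12)** — a 2D filter bank with wavelengths
  {3, 3√2, 6, 6√2, 12} pixels (a half-octave ladder from the minimal
  wavelength 3) and six orientations kπ/6, envelope σ = 0.56λ, aspect 0.5,
  zero-mean real part (responses ignore the DC level). The mean magnitude
  response over masked pixels is pooled over slices; features are the
  per-orientation mean and SD across the five scales. Note that on a
  square lattice the orientation responses to broadband noise are not
  exactly isotropic near the Nyquist wavelength; the tests allow for this
  lattice anisotropy.

Numerical conventions for degenerate matrices: log terms use log₂ with
0·log 0 ≡ 0; correlation-type GLCM features with zero marginal variance
return 1; NGTDM uses ε = 10⁻¹² with coarseness capped at 10⁶, and its
pairwise features are 0 when only one level is occupied.

## ComBat harmonisation

`combat_fit()` implements the parametric empirical-Bayes location/scale
model: per feature, data are standardised by the batch-design fit (grand
mean weighted by batch size; pooled variance of residuals around batch
means, divisor n); per-batch raw location/scale estimates are shrunk
toward feature-wide normal and inverse-gamma priors estimated by method of
moments, iterating the standard fixed-point updates to tolerance 10⁻⁴
(cap 100 iterations; typically < 10 suffice). A single batch yields the
identity transform. The implementation agrees with the reference
Bioconductor implementation to the iteration tolerance, which one test
verifies independently.

`combat_fit(protect = "label")` adds the class label to the
standardisation design so batch location/scale estimates are not
contaminated by unequal class composition across batches. The protected
column is used only at fit time; `combat_apply()` never reads labels, so
held-out data are transformed leakage-free. Protection is off by default:
it feeds training labels into the learned transform, which is a deliberate
trade-off to be made explicit, not a silent default.

In every cross-validated benchmark the ComBat model is fitted on the
training folds only and applied to the held-out fold — harmonising train
and test jointly would leak distributional information, so the
leakage-safe protocol is the default even though it is stricter than
common practice.

## Classifier benchmarking

`run_benchmark()` evaluates logistic regression (ridge-penalised,
C ∈ {0.01, 0.1, 1, 10}), RBF-SVM (C ∈ {0.1, 1, 10}, γ = (1/p)·{0.1, 1, 10},
Platt-calibrated probabilities), random forest (100/300 trees, depth
∞/5/10) and gradient boosting (100/300 rounds, learning rate 0.05/0.1,
depth 2/3) on raw versus fold-wise harmonised features. LR and SVM see
features standardised with training-fold statistics; the tree ensembles see
raw features. Hyperparameters are chosen by inner 3-fold CV on AUC. Folds
are stratified by class and grouped by case (all rows — or slices — of a
case share a fold), with per-fold class counts within one case of the
global proportions.

Metrics: AUC by the Mann–Whitney construction (ties ½; undefined AUC is
reported as missing, never 0), sensitivity/specificity/precision/F1 at a
threshold, fold-level mean ± SD (unweighted over folds), DeLong's
structural-components test for correlated AUCs on pooled out-of-fold
scores, continuity-corrected McNemar and χ² on binary predictions, and a
threshold sweep over a 0.01-step grid. The operating-point selector
returns the largest grid threshold at or below the standard 0.5 whose
sensitivity meets the target (default 100%) — i.e. the result of lowering
the decision threshold until no malignant case is missed, which trades
specificity for sensitivity exactly as a rule-out test requires.
Degenerate DeLong comparisons (zero estimated variance) return p = 1 when
the AUCs are equal and p → 0 otherwise, with a flag.

## The CNN baseline

The image arm crops every mask-bearing axial slice to its bounding box
(10% margin per side), resizes to a square matrix (224×224 by default) by
bilinear interpolation, and z-scores each slice (population SD). The
network is three blocks of [3×3 conv → batch-norm → ReLU → 2×2 max-pool →
dropout] with widths 8/16/32, then flatten → dense(32, ReLU) → dropout →
dense(1, sigmoid). Training uses Adam (10⁻³), minibatch 16, class weights
inverse to slice-class frequency, optional flip/±10% zoom/±15°
rotation/±10% shift augmentation, and early stopping (patience 10) when a
validation set is supplied; all of this runs in base R with im2col
convolutions and is checked against finite-difference gradients. Held-out
case scores are the mean probability over the case's slices (the
aggregation is a package choice; the alternative, max-pooling over slices,
is more sensitive to single-slice false positives). Optimiser, learning
rate and epoch budget are package choices frozen in the defaults.

Phantom experiments in the tests use 32×32 slices and widths 4–32: at
desk scale this keeps a full cross-validated CNN run in minutes on one
CPU while preserving the architecture. The capacity check (training
accuracy ≥ 95% on a 20-case cohort within 50 epochs) runs with dropout
disabled and learning rate 2·10⁻³: peripheral slices of malignant lesions
contain no visible internal structure, so reaching near-perfect training
accuracy requires memorisation, which regularisation is designed to
prevent.

## The phantom cohort: what it emulates, and what it does not

`phantom_spec()` generates ellipsoidal lesions (semi-axes uniform in a
configurable range, random orientation) on a noisy background.
Benign lesions are near-constant signal plus correlated Gaussian noise
whose amplitude varies from lesion to lesion (×0.7–1.8), because benign
lipomas are not uniformly bland. Malignant lesions add 2–8 hyperintense
Gaussian blobs (σ 1.5–4 voxels) and 1–3 hypointense septum-like planes,
with a per-case severity factor (uniform 0.3–1) scaling all amplitudes —
so the classes genuinely overlap and no single feature separates them,
as in the clinical problem. `class_texture_gap` (default 1.2) scales the
malignant structure globally; at 0 the label is uninformative by
construction.

Batch effects are injected at the image level, not the feature level:
per-batch multiplicative gain (default 1 vs 1.5), additive offset (0 vs
30), and Gaussian blur (0.2 vs 1.2 voxels), each with scanner-level
per-case jitter (log-normal gain SD 0.3; offset SD 15; blur SD 0.35),
reflecting that a "batch" defined by fat-suppression technique pools many
centres and systems that share a tendency, not a protocol. Gain and
offset move histogram and Gabor features; blur moves the quantized-texture
features (which are gain/offset-invariant by construction). With
`confounding = 0` batches are dealt round-robin within class
(independence by construction); `confounding = c` moves each case with
probability c to its class-preferred batch.

Default sizes: the `"paper-like"` preset is a 145-case, two-batch cohort
(68 benign / 77 malignant, 64×64×48 voxels at 1×1×2 mm, confounding 0.1 —
a batch variable defined by pulse-sequence choice has no strong reason to
track malignancy). Tests and the acceptance script use scaled-down
cohorts (20–60 cases, ~36³ voxel grids, N~g~ ∈ {8, 16}) so the full suite
runs in minutes on one CPU; the methods are size-agnostic.

The phantom does **not** emulate MR physics (coil profiles, bias fields,
k-space artefacts), anatomy outside the lesion, multi-sequence imaging, or
segmentation variability. Passing tests demonstrate that the pipeline's
machinery is correct and that its statistical behaviour matches theory on
data with known ground truth — not that any particular accuracy will be
achieved on patients.

## Harmonisation under class–batch confounding: a structural limit

The phantom experiments reproduce the expected qualitative behaviour when
class and batch are independent or mildly associated: image-level batch
effects degrade cross-batch feature comparability, and fold-wise ComBat
recovers classifier AUC (consistently positive paired differences across
replicate cohorts), while under a no-batch-effect null the correction
changes AUC by little.

Under *strong* confounding the picture reverses, and the package's
experiments document why. When ~90% of malignant cases sit in one batch,
the batch effect itself becomes a 90%-reliable proxy for the label; a
boosted tree can infer batch membership from gain-shifted intensity
features and exploit it, so the raw-feature arm is
information-advantaged. Meanwhile unprotected ComBat equalises batch means
that now contain mostly class signal, removing it (per-feature class AUCs
collapse toward chance), and even label-protected ComBat must estimate
batch effects from the few off-diagonal cases. In this regime corrected
and raw arms differ by only a few AUC points with either sign. This is a
property of the estimation problem, not of the implementation — the same
reversal is predicted by an information argument and observed across a
wide range of generator settings. Practically: harmonisation should be
paired with a check of class–batch balance, and protection of biological
covariates considered whenever composition differs across batches.

## Error handling and edge cases

Degenerate inputs fail loudly: lesions that do not fit the grid name the
offending axis; quantization refuses masks with fewer distinct intensities
than levels; ComBat refuses single-case batches, zero-variance features
and unseen batch labels; classifiers refuse single-class training data;
constant images cannot be z-scored (callers skip such slices). Extreme
anisotropy (ratio > 20) and lesions thinner in-plane than the largest
Gabor wavelength produce warnings, not errors.
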