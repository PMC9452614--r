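# liporad

Benign lipomas and atypical lipomatous tumours (ALTs, low-grade
liposarcomas) overlap on MRI, so distinguishing them currently requires
biopsy. A widely studied alternative is to quantify the lesion with
radiomic texture descriptors and train a classifier on them — but
multicentre MRI cohorts are acquired under heterogeneous protocols, and
this technical ("batch") variation confounds the features unless it is
statistically harmonised.

`liporad` implements that workflow end to end, for radiologists'
quantitative-imaging teams and for methodologists studying batch effects in
radiomics:

* **3D radiomic features** — a fixed, ordered catalog of 92 descriptors:
  shape (14), intensity histogram (14, 256 bins), GLCM (21), GLRLM (13),
  GLSZM (13), NGTDM (5) and Gabor filter-bank features (12). Gray levels are
  discretised by **equal-probability quantization** (thresholds at the
  k/N<sub>g</sub> empirical quantiles) at N<sub>g</sub> ∈ {8, 16, 24, 32,
  40, 48, 64}; GLCM/GLRLM use the four in-plane directions (0°, 45°, 90°,
  135°) at offset 1; GLSZM/NGTDM use 26-connectivity; matrix features are
  averaged over directions and then over N<sub>g</sub>. Formulae follow the
  IBSI definitions.
* **ComBat harmonisation** — parametric empirical-Bayes location/scale
  batch correction, `x = α + γ_batch + δ_batch·ε`, with method-of-moments
  priors and the standard fixed-point shrinkage updates; optional protection
  of the class label in the design matrix.
* **Classifier benchmarking** — logistic regression, RBF-SVM, random
  forest and gradient boosting, compared on raw versus fold-wise harmonised
  features under patient-grouped stratified 10-fold cross-validation, with
  AUC/sensitivity/specificity (mean ± SD over folds), DeLong tests for
  correlated AUCs, McNemar/χ² comparisons, and decision-threshold sweeps.
* **A from-scratch CNN baseline** — three blocks of
  conv → batch-norm → ReLU → max-pool → dropout, then dense(32)+ReLU →
  dropout → sigmoid, trained on z-scored 224×224 lesion crops with
  flip/zoom/rotate/shift augmentation and class weights. Implemented in
  base R (im2col convolutions) and validated by finite-difference gradient
  checks.
* **A synthetic phantom cohort** — ellipsoidal lesions whose malignant
  variants carry nodular inclusions and septum-like planes, with per-batch
  gain/offset/blur acquisition effects and scanner-level jitter, so the
  whole pipeline is testable with known ground truth and no patient data.

## Worked example

```r
library(liporad)

spec <- phantom_preset("small", seed = 42)
spec
#> Phantom cohort spec: 20 cases, 10 malignant / 10 benign, 2 batch(es)
#>   grid 28x28x26  spacing 1x1x1 mm
#>   texture gap 1.2  confounding 0  seed 42
#>   batch gain 1/1.5  offset 0/30  blur 0.2/1.2

man   <- generate_cohort(spec, "phantom_demo")
feats <- extract_cohort(man, extraction_config(ng_levels = c(8, 16)))
round(feats[1:3, c("glcm_contrast", "ngtdm_strength", "hist_variance")], 2)
#>   glcm_contrast ngtdm_strength hist_variance
#> 1          6.16           0.58       2716.62
#> 2          7.05           0.54      11337.43
#> 3          7.29           0.40         87.91

bench <- run_benchmark(feats, k = 4, seed = 7, classifiers = c("lr", "gb"),
                       grids = list(lr = data.frame(C = 1),
                                    gb = data.frame(nrounds = 100, eta = 0.1,
                                                    max_depth = 2)))
bench
#> Classifier benchmark (k = 4 grouped folds, seed 7)
#>
#>    dataset classifier         AUC sensitivity specificity
#>        raw         LR 0.79 ± 0.25 0.54 ± 0.42 0.50 ± 0.43
#>        raw         GB 0.56 ± 0.23 0.71 ± 0.21 0.33 ± 0.47
#>  corrected         LR 0.79 ± 0.32 0.83 ± 0.33 0.62 ± 0.28
#>  corrected         GB 0.62 ± 0.28 0.25 ± 0.32 0.67 ± 0.47
#>
#> DeLong corrected vs raw (pooled out-of-fold scores):
#>  classifier AUC_corr AUC_raw    p
#>          LR     0.76   0.710 0.44
#>          GB     0.65   0.595 0.75
```

Rows 1–3 are three phantom lesions: GLCM contrast and NGTDM strength read
out internal texture heterogeneity (higher for lesions with nodular
structure), and `hist_variance` mixes lesion heterogeneity with the batch
gain. The benchmark grid is one row per classifier × feature-set arm; at
this 20-case demo scale the fold-level metrics are deliberately noisy —
the per-fold SDs say so — and larger cohorts (e.g.
`phantom_preset("paper-like")`, 145 cases) give stable estimates.

The full pipeline (simulate → extract → harmonise → benchmark → CNN →
report bundle) is one call:

```r
run_pipeline(phantom_preset("paper-like", seed = 1), "out/", seed = 1)
```

or, from a shell, `Rscript inst/cli/liporad.R run-all --preset paper-like
--seed 1 --out out/`.

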