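# habitomics

An end-to-end, fully testable **habitat-radiomics pipeline** for
predicting a binary molecular label — the motivating use case is EGFR
mutation status in stage I non-small cell lung cancer — from CT volumes of
small lung nodules. It is aimed at imaging researchers who want every
stage of a habitat-radiomics analysis (region construction, feature
extraction, feature selection, modeling, evaluation) as composable,
deterministic R functions that can be validated on synthetic phantoms
before being pointed at patient data.

## What it computes

Given an image volume `x` (HU) with tumor mask `M` and voxel spacing `s`:

1. **Preprocessing** — intensities clipped to `[-800, 800]` HU, then
   resampled to isotropic 1 mm³ (tri-linear for intensities,
   nearest-neighbour for the mask).
2. **Regions** — peritumoral shells `dilate(M, r) \ M` for
   r ∈ {1, 3, 5} mm (Euclidean, anisotropy-aware), and **habitats**: each
   in-tumor voxel gets 13 local statistics of its 3×3×3 neighbourhood
   (mean, median, min, max, range, variance, SD, skewness, kurtosis,
   energy, entropy, uniformity, CV); k-means (k = 3, k-means++ seeding,
   10 restarts) on z-scored channels partitions the tumor into habitat
   subregions.
3. **Features** — an IBSI-style bank per region: 14 shape descriptors
   (marching-tetrahedra mesh), 18 first-order statistics and 75 texture
   features (GLCM 24, GLRLM 16, GLSZM 16, GLDM 14, NGTDM 5), repeated on
   Laplacian-of-Gaussian and stationary Haar wavelet transforms of the
   image.
4. **Selection** — the five-stage cascade
   ICC(2,1) ≥ 0.85 → z-score → Welch t-test (p < 0.05) → greedy Pearson
   de-correlation (|r| ≤ 0.9) → mRMR (MID criterion) → L1-penalized
   logistic regression (cross-validated λ).
5. **Models** — per-region signatures with stratified five-fold
   cross-validated grid search (LR, MLP, RF, SVM, XGBoost, Extra-Trees),
   univariable/stepwise-multivariable clinical logistic analysis, and a
   fusion **nomogram** (logistic model over signature scores + smoking,
   re-encoded on a 0–100 points scale that round-trips the probability
   exactly).
6. **Evaluation** — AUC with DeLong 95% CI, paired DeLong tests,
   Hosmer–Lemeshow calibration (deciles of risk, χ², df = g − 2),
   calibration bins, and decision-curve analysis
   `NB(p_t) = TP/n − FP/n · p_t/(1 − p_t)`, plus the cosine-decay
   learning-rate schedule used for transfer-learning fine-tuning.

Because no patient data ship with the package, a first-class
**synthetic-data module** generates phantom cohorts — spherical nodules
with planted intensity plateaus (habitat ground truth), class-conditional
clinical covariates mirroring a real multicenter baseline profile (63.8%
mutant; smoking 22.8% vs 47.4%; female 65.5% vs 44.3%), and a designated
texture parameter shifted by a chosen effect size `d`, so the Bayes AUC
is known in closed form: `Φ(d/√2)`.

## Worked example

```r
library(habitomics)

spec <- phantom_spec(grid_shape = c(40, 40, 40), nodule_radius_mm = 8,
                     n_plateaus = 3, plateau_levels = c(-400, -150, 100),
                     noise_sd = 20)
vol <- preprocess_volume(generate_phantom(spec, seed = 1))
vol
#> <annotated_volume> 40x40x40 voxels, spacing 1x1x1 mm, 2109 mask voxels

rs <- region_set(vol, seed = 1)
table(rs$habitat_labels[rs$tumor_mask])
#>   1   2   3
#> 763 583 763

tidy <- extract_feature_table(vol, rs = rs,
                              transforms = list(original = vol))
table(tidy$family[tidy$region == "intra"])
#> firstorder   glcm   gldm  glrlm  glszm  ngtdm  shape
#>         18     24     14     16     16      5     14
```

The nodule of 2109 voxels is partitioned into three habitats of 763, 583
and 763 voxels (core/mid/rim plateaus), and the intratumoral region
yields the full 14 + 18 + 75 feature bank. Downstream, on a tabular
cohort with a planted effect `d = 1.5`:

```r
sim <- simulate_feature_table(300, d = 1.5, n_noise = 20, seed = 1)
tab <- data.frame(sample_id = sprintf("S%03d", 1:300), sim$features)
rep_ <- run_selection_cascade(tab, sim$labels, mrmr_k = 10, seed = 1)
rep_
#> <selection_report> stages:
#>   input   : 21 features
#>   icc     : 21 survivors
#>   ttest   : 2 survivors
#>   pearson : 2 survivors
#>   mrmr    : 2 survivors
#>   lasso   : 1 survivors

m <- train_signature(tab[, c("sample_id", rep_$stages$lasso)],
                     sim$labels, "lr", seed = 1)
roc_auc(m$scores, sim$labels)
#> training AUC 0.870 (95% CI 0.829-0.911)
```

The cascade isolates the planted feature out of 21 and the signature's
AUC of 0.870 sits just above the cohort's Bayes AUC Φ(1.5/√2) = 0.856 on
the training partition (cross-validated AUC approaches it from below) —
the behaviour the recovery tests assert.

The whole run — simulate → preprocess → regions → extract → select →
train → evaluate — is driven by `run_pipeline(default_run_config(...))`
with a YAML-serializable configuration, a resumable per-stage manifest
(MD5 hashes, timings), and an `Rscript` wrapper in `inst/scripts/`.

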