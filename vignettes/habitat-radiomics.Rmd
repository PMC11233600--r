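---
title: "Habitat radiomics on synthetic phantoms: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat radiomics on synthetic phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem and the pipeline

Activating EGFR mutations define the targetable subgroup of early-stage
non-small cell lung cancer, but small resectable lesions are exactly the
ones where biopsy material for molecular testing is scarce. Habitat
radiomics asks whether the *internal organisation* of a nodule on CT —
spatially coherent subregions with distinct local texture, plus the
tissue immediately surrounding the lesion — carries that molecular
label. This package implements the full analysis as composable stages:

intensity standardisation → peritumoral shells and habitat subregions →
an IBSI-style feature bank per region and image transform → a five-stage
feature-selection cascade → per-region signature models and a fusion
nomogram → discrimination, calibration, and net-benefit statistics.

Every stage is exercised end-to-end on synthetic 3D phantoms with known
ground truth, so the pipeline's statistical behaviour (what it recovers,
at what rate it false-alarms) is verified by construction before any
real data are involved.

# Preprocessing

Two standardisation steps, in a fixed order:

* **Clipping** to [−800, 800] HU bounds the influence of extreme values
  (air, bone, artefacts). Total and idempotent.
* **Isotropic resampling** to 1 mm³ removes scanner-dependent voxel
  anisotropy. Intensities are interpolated tri-linearly; the mask is
  resampled nearest-neighbour and re-binarised at 0.5. Both orders are
  configuration fields, since reasonable alternatives exist
  (e.g. B-spline intensities, linear mask with threshold).

A numerical detail that matters: nearest-neighbour indices are computed
by rounding *half up*, not by `round()`. IEEE ties-to-even makes
alternate source voxels cover 3 versus 1 output voxels whenever the
spacing ratio is an integer, which biases the resampled mask volume by
>10%; half-up rounding restores uniform coverage, and the mask-volume
preservation test (< 5% change for a sphere resampled 2 mm → 1 mm)
guards it.

# Regions

**Peritumoral shells.** The ROI is dilated by a Euclidean ball of radius
1, 3, 5 mm in *physical* units (anisotropy-aware offset enumeration) and
the ROI subtracted, so each shell is disjoint from the tumor by
construction. Dilation is tested against a brute-force all-pairs
distance oracle; reaching the grid boundary warns with the clipped voxel
count.

**Local feature map.** Every in-tumor voxel receives 13 statistics of
its 3×3×3 neighbourhood: mean, median, minimum, maximum, range,
variance, SD, skewness, kurtosis, energy (Σv²), histogram entropy (fixed
25 HU bins, bits), uniformity, and coefficient of variation.
Neighbourhoods are restricted to the VOI by default — local features
describe tumor tissue, not the adjacent parenchyma, whose −800 HU
background would otherwise dominate every boundary voxel's statistics.
The median is the *lower* median so that, on discrete plateau data, it
always equals an actually-occurring value.

**Habitats.** K-means (k = 3) on z-scored channels, k-means++ seeding,
10 restarts, Lloyd iterations; clusters are renumbered by increasing
mean local intensity so labels are deterministic, and empty clusters are
permitted and reported.

*Which channels drive the clustering* was the one genuinely open design
decision, and it is settled by an argument worth recording. About seven
of the 13 channels (range, variance, SD, skewness, kurtosis, entropy,
uniformity/CV, and the size-dependent energy) measure *local
dispersion*. On any piecewise-constant image these channels are ~0
inside a tissue class and take extreme values exactly on the one-voxel
interface layer between classes; after z-scoring, that interface layer
becomes a tight, far-away cluster in 7 of 13 dimensions. The k-means
within-SS optimum then separates *interface from interior* rather than
tissue class from tissue class — we measured adjusted Rand indices of
0.2–0.5 against planted partitions on noiseless phantoms of every
geometry tried, a failure mode that no amount of class separation fixes
(the interface signal grows with the class contrast). Clustering
therefore defaults to the *location* channels (mean, median), which are
affine-equivariant in intensity — this also makes the habitat stage
exactly invariant to global intensity shifts after z-scoring. All 13
channels are always emitted, and `channels = NULL` selects the full set
for users who want dispersion-driven habitats.

# The synthetic-data module

`generate_phantom()` builds a spherical nodule (physical-distance mask)
inside uniform lung background, partitioned into `n_plateaus` internal
intensity plateaus with additive Gaussian acquisition noise over the
whole field of view (with `noise_sd = 0` the image is exactly piecewise
constant). Three plateau geometries are available:

* **slabs** (default): axial bands of whole voxel layers with near-equal
  voxel counts;
* **shells**: radial core/mid/rim;
* **blobs**: nearest-seed Voronoi cells.

Slabs are the default because their planar interfaces make the planted
partition *unambiguous under windowed statistics*: every voxel has a
strict in-window majority of its own class, so its window median equals
its own plateau level and exact recovery (ARI = 1.0) is attainable and
attained. Curved interfaces (shells, blobs) necessarily carry a
single-voxel layer of formally ambiguous voxels whose windows are
majority-foreign; iterating a window-median relabelling to fix them is a
discrete curvature flow that erodes spherical shells entirely. The
generator still regularises multi-plateau partitions to a median-stable
fixpoint (a no-op for slabs) and warns if a plateau is eliminated.

`generate_cohort()` draws labels Bernoulli(`mutant_fraction`), derives
one child RNG stream per sample (labels and child seeds first, then each
sample generated in isolation — bit-reproducible and parallelisable),
and samples clinical covariates. The defaults are the study conditions
the simulator emulates: 63.8% mutant; smoking history 22.8% in mutants
vs 47.4% in wild-type; female 65.5% vs 44.3%; age ~ N(60, 9²); stage,
CT pattern, histology and lobe are label-independent (only smoking
survives multivariable clinical analysis in the emulated setting, so
only smoking and its correlate gender carry class information). One
designated texture-bearing parameter — the plateau contrast, mean
250 HU, within-class SD 50 HU — is shifted by `effect_size_d`
within-class SDs for mutants. With a single Gaussian carrier the cohort
Bayes AUC is `pnorm(d / sqrt(2))` in closed form, which anchors the
recovery tests: the cross-validated pipeline AUC must approach it from
below.

What the phantoms do **not** emulate: lung anatomy, ground-glass
attenuation physics, partial-volume effects, scanner-specific noise
spectra, or any image-level correlate of mutation status in the
*peritumoral* tissue — shell features are label-null by construction, so
peritumoral signatures on synthetic cohorts are honest null models.
Passing tests therefore demonstrate that the machinery recovers known
signal at known rates, not that any particular real-data AUC is
reproducible.

# The feature bank

**Shape (14).** Mesh volume, voxel volume, surface area,
surface/volume, sphericity, maximum 3D diameter, three maximum in-plane
2D diameters, PCA axis lengths (4√λ), elongation, flatness. Area and
volume are measured by *marching tetrahedra* (six tetrahedra per cell
sharing a main diagonal — table-free, watertight) on the 3×3×3
box-smoothed indicator field, with linearly interpolated crossings. The
smoothing matters: with all-midpoint crossings on the raw binary mask
the faceted surface overestimates a sphere's area by ~30% and sphericity
plateaus near 0.78. Measuring area *and* volume on the same smoothed
mesh makes the pair describe one polyhedral solid, so the isoperimetric
inequality bounds sphericity by 1 — digitised balls give 0.975 (r = 5 mm)
rising to 0.994 (r = 20 mm), approaching 1 from below as the tests
require. The cost is that mesh measures describe the slightly rounded
solid (mesh volume < voxel volume, edges of polyhedra chamfered); the
raw midpoint mesh remains available (`smooth = FALSE`) and tracks sharp
cuboids to within a few percent. Degenerate masks (single voxel, lines)
return finite values with a `degenerate` flag; elongation/flatness
default to 1 when the leading eigenvalue vanishes.

**First order (18).** Energy, total energy, entropy and uniformity (on
discretised levels), min, p10, p90, max, mean, median, IQR, range, mean
absolute deviation, robust MAD (10–90% window), RMS, skewness, kurtosis
(not excess-corrected), population variance. Constant regions use the
convention skewness = kurtosis = 0.

**Texture (75).** GLCM (24, symmetric, averaged over the 13 unique 3D
directions), GLRLM (16, averaged likewise), GLSZM (16, 26-connected
zones), GLDM (14, dependence = 26-neighbours with identical level,
α = 0), NGTDM (5). Discretisation defaults to fixed 25 HU bins anchored
at the region minimum; a fixed-bin-count mode is available. Degenerate
conventions: a single-level region has GLCM correlation and MCC 1,
contrast 0, and NGTDM coarseness capped at 10⁶. Every one of the 93
first-order/texture features is tested to 1e-9 against a literal-formula
oracle (explicit voxel-pair enumeration, flood fill, nested loops) on
random 5³ images.

**Transforms.** Feature re-extraction on: scale-normalised
Laplacian-of-Gaussian responses (σ in mm, separable Gaussian-derivative
kernels sampled at physical coordinates, zero-sum-corrected so constants
map to exactly 0; σ ∈ {1, 2} mm by default, skipped with a warning if σ
exceeds the ROI extent) and the 8 sub-bands of a single-level
*undecimated* 3D Haar wavelet (LLL…HHH, same grid as the input so masks
stay aligned; the Haar pair was chosen as the canonical two-tap wavelet
with an exactly-zero high-pass response on constants). Shape features
are geometry-only and computed once per region under the original
transform.

# The selection cascade

Fixed order, strictly nested survivors, all statistics from training
samples only (an audit test perturbs held-out rows and asserts the
report is byte-identical):

1. **ICC filter** — ICC(2,1), the two-way random-effects,
   absolute-agreement, single-measurement form, against a test–retest
   table; threshold 0.85. The retest table is synthesised by a one-voxel
   segmentation perturbation (6-connected erosion, or 1 mm dilation when
   erosion would empty the mask), mimicking segmentation uncertainty.
   Zero-variance features have undefined ICC and are dropped with a
   reason.
2. **Z-score + Welch t-test** — retain p < 0.05; zero-variance features
   get p = 1 by convention; standardisation parameters are stored for
   leak-free reuse on held-out partitions.
3. **Greedy Pearson de-correlation** — repeatedly delete, from the pair
   with the largest |r| > 0.9, the member with the larger mean |r| to
   all remaining features; ties broken by feature-name order; terminates
   with max pairwise |r| ≤ 0.9. The 0.9 threshold is a package default
   (config-exposed), chosen as the common radiomics practice.
4. **mRMR** — greedy forward selection with the difference (MID)
   criterion, mutual information on equal-frequency tertile-discretised
   features, ties broken by name order, k = 30 by default (enough to
   hand the Lasso a stable over-complete set without re-admitting the
   redundancy the previous stage removed). Each greedy step is tested
   against exhaustive criterion evaluation.
5. **Lasso** — L1-penalised logistic regression over a cross-validated
   λ path (stratified five-fold, deviance loss), survivors = nonzero
   coefficients at λ-1SE (the sparser, more stable choice; λ-min is an
   option), with coefficient proportions reported. An all-zero solution
   returns an empty set; a single input feature is returned with its
   unpenalised coefficient.

# Models and the nomogram

`train_signature()` grid-searches hyperparameters by stratified
five-fold cross-validated AUC and refits the best point on the full
training set; six algorithm families are supported (logistic regression,
MLP via nnet, random forest, RBF-kernel SVM, XGBoost, and extremely
randomised trees via ranger). All fits are seeded; the determinism
contract (same seed ⇒ identical grid point and scores) is tested.
Signature scores are positive-class probabilities in [0, 1].

`clinical_analysis()` reports univariable logistic odds ratios with Wald
95% CIs and a p-value-driven stepwise multivariable model (enter
p < 0.05, remove p > 0.10). Multi-category covariates are integer-coded
so the report prints one OR per characteristic; this single-slope
parameterisation is a documented simplification — for a binary covariate
the univariable OR is exactly the 2×2 cross-product ratio, which the
tests assert. Quasi-separation is flagged rather than fatal.

`build_nomogram()` fits the fusion logistic model over signature scores
plus smoking and re-encodes it on a points scale: each predictor's
points are an affine map of its value anchored at the range end where
its contribution is smallest, scaled so the largest coefficient×range
spans 100 points. The total-points → probability map is an exact affine
re-encoding of the linear predictor (round-trip tested at 1e-9);
constant predictors contribute zero points, and aliased (collinear)
coefficients are zeroed with a warning.

# Evaluation statistics

* **AUC** is the Mann–Whitney U statistic with ties counted ½ (equal to
  the trapezoidal ROC area), CI from the DeLong structural-component
  variance; equality with all-pairs counting and with an independent
  reference implementation is tested.
* **Paired DeLong test** from the same components; checked against a
  2000-resample paired bootstrap (agreement within 0.02) and against the
  reference implementation at 1e-9.
* **Hosmer–Lemeshow**: deciles of risk, χ² = Σ(O−E)²/(E(1−E/n_g)),
  df = g − 2 (the df convention assumes fitted probabilities; the size
  test simulates exactly that). Degenerate groups are merged with a
  neighbour and the df adjusted.
* **Decision curves**: net benefit per model over thresholds 0.01–0.99
  (step 0.01), with treat-all and treat-none references; the bound
  NB ≤ prevalence is property-tested.
* Operating points for accuracy/sensitivity/specificity/PPV/NPV default
  to the Youden-optimal threshold *frozen on training data*.
* `cosine_lr()` implements the cosine-decay learning-rate schedule with
  a task-specific mode and a backbone mode that stays at 0 for the first
  half of training (frozen pretrained backbone), for reuse by any
  transfer-learning extension. The deep-learning signature slot in the
  pipeline is a pluggable per-sample score column; the shipped
  placeholder is a logistic score on summary statistics of the
  maximum-area tumor slice, *not* a neural network.

# The pipeline

`run_pipeline(config)` executes simulate → preprocess → regions →
extract → select → train → evaluate inside a run directory, with a JSON
manifest recording each stage's outputs, MD5 hashes and timing. A stage
whose outputs are intact is skipped on re-run, so deleting one stage's
outputs resumes from exactly there; a failing stage names itself and
preserves earlier results. The configuration round-trips through YAML
and holds every stage parameter and the single root seed from which all
randomness derives.

# Problem sizes used by the test-suite

The suite verifies statistical behaviour at sizes chosen to keep the
full run in a few minutes on one core while leaving Monte-Carlo margins
comfortable: oracle equivalence on 5³ images (20 seeds, tol 1e-9);
habitat recovery on 23³–31³ phantoms; type-I error of the t-test filter
on 200 replicates of 50 null features; Hosmer–Lemeshow size on 100
fitted-model replicates of n = 1000; the Bayes-AUC recovery on 20
tabular cohorts of n = 300 (d = 1.5 against Φ(d/√2) = 0.856, and d = 0
against 0.5); and an image-based end-to-end pipeline run at n = 14 on
20³ grids, twice, asserting byte-identical evaluation reports.

# Known limitations

* Mesh-based shape measures describe the box-smoothed iso-surface:
  self-consistent (sphericity ≤ 1 by construction) but systematically
  smaller than sharp-solid values for masks only a few voxels across.
* The habitat-clustering default (location channels) is the right choice
  for piecewise-constant-like heterogeneity; textures whose classes
  differ in dispersion rather than level need `channels = NULL`.
* Shell features on synthetic cohorts are null by design; the
  peritumoral arm is exercised structurally, not for discrimination.
* The clinical analysis' integer coding of ordered multi-category
  covariates assumes a common slope across adjacent levels.
* No DICOM ingestion; NIfTI only. No neural-network training; the
  deep-learning signature is an interface with a linear placeholder.
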