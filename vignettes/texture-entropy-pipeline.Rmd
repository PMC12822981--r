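---
title: "Multiscale entropy texture analysis of tumor ROIs: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale entropy texture analysis of tumor ROIs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(texent)
```

`texent` asks a simple radiological question in a testable form: do two
tissue classes differ in the *texture* of small grayscale MRI patches, and
can that difference support a classifier that generalizes to unseen
patients? This vignette documents the models the package implements, the
parameters that matter, what the synthetic data generator does and does not
emulate, and the design decisions taken where more than one defensible
choice existed.

## The five 2D entropy measures

All five measures operate on `m × m` pixel windows of a (possibly
coarse-grained) image and quantify how unpredictable the local texture is.

**Sample entropy (SampEn2D).** Windows of side `m` are taken at every
position where an `(m+1)`-window also fits, so both template sizes share
one support. A pair of windows *matches* when every pixelwise difference is
at most the tolerance `r` (Chebyshev distance). With `B` matched pairs at
size `m` and `A` at size `m+1`, `SampEn2D = −ln(A/B)`. Self-matches are
excluded; pairs are counted once. Because the `m`-window nests inside the
`(m+1)`-window, `A ≤ B` and the value is non-negative. If `A` or `B` is
zero the statistic is undefined; the package returns `NA` with a warning
rather than an infinite value, and feature assembly imputes 0 with a
logged warning so downstream tables stay rectangular.

**Fuzzy entropy (FuzzEn2D)** replaces the hard threshold with the
membership `exp(−d^n / r)` evaluated on *mean-centered* windows, making the
statistic smooth in `d` and insensitive to local brightness. It is always
defined because every pair contributes a positive similarity.

**Permutation entropy (PermEn2D)** encodes each window by the ordinal
pattern of its pixels — flattened row-major, ranked with a stable
tie-break (earlier index wins) — and reports the Shannon entropy of the
pattern distribution normalized by `ln((m²)!)`, so values live in [0, 1].
The flattening order is part of the definition: with tied pixel values,
row-major and column-major flattening produce genuinely different pattern
distributions.

**Dispersion entropy (DispEn2D)** maps pixels through the normal CDF
(location = image mean, spread = population SD), rounds linearly into `c`
classes, and normalizes the Shannon entropy of the windowed class patterns
by `ln(c^(m²))`. The CDF step standardizes location and scale, so DispEn2D
is invariant under any increasing affine intensity map. A constant image
(zero SD) maps every pixel to the middle class and scores 0.

**Distribution entropy (DistEn2D)** histograms the Chebyshev distances of
all unordered window pairs into `bins_B` equal-width bins spanning
[0, max distance] and reports the normalized (log2) Shannon entropy of that
histogram.

### Multiscale profiles

Coarse-graining replaces each non-overlapping `s × s` block by its mean and
drops trailing rows/columns; applying an entropy at `s = 1…5` yields a
five-point profile per measure, 25 features per image. The tolerance for
SampEn2D and FuzzEn2D is fixed once as `r_factor ×` (population SD of the
scale-1 image) and held across scales — the standard multiscale convention
that keeps scales comparable. For a constant image the tolerance falls back
to `r_factor` itself, which leaves all entropies at their correct value of
zero.

Two numerical consequences of the fixed tolerance are worth knowing:

* For truly i.i.d. noise, coarse-grained template matches become *rare*:
  block means concentrate while `r` stays anchored to the scale-1 SD, so
  `A` can hit zero and SampEn2D becomes undefined at coarse scales, and
  defined values need not decrease with `s`. The classical
  "block-averaging lowers complexity" intuition is tested in the suite on
  the normalized pattern measures (PermEn2D, DispEn2D), which are immune
  to this artifact.
* The number of window pairs falls as `(HW/s²)²`. Below roughly 96×96
  input pixels the coarsest scale of a noisy image no longer has enough
  pairs for a stable SampEn2D; package tests that assert per-scale
  behavior therefore use 96×96 ROIs, while tests that only need aggregate
  class separation run at 32×32 for speed. The generator default remains
  128×128, the typical annotated-mask size.

### Defaults

`entropy_params()` fixes `m = 2`, `r_factor = 0.2`, `fuzzy_n = 2`, `c = 4`,
`bins_B = 64`, `scales = 1:5` — the standard values in the 1D/2D entropy
literature. None of these is data-tuned; all are recorded with extracted
features and exposed in the configuration.

## Statistical and radiomic features

The 17 first-order and 73 gray-level-matrix features follow the standard
(IBSI-style) definitions; the exact name lists are frozen in the package
documentation as its contract (17 FOS, 22 GLCM, 14 GLDM, 16 GLRLM,
16 GLSZM, 5 NGTDM). Choices the formulas do not pin down:

* **Quantization**: fixed bin *count* `L = 32`, equal-width over each ROI's
  own min–max; the maximum maps to level `L`, constant images to level 1.
* **Directions**: distance-1 offsets in the four unique 2D directions;
  co-occurrence matrices symmetrized and normalized per direction;
  per-direction features averaged (not merged).
* **GLDM**: dependence = number of 8-neighbors within `alpha = 0` gray
  levels; the dependence-size index is dependence + 1.
* **NaN policy**: undefined features (zero-variance correlation,
  skewness/kurtosis of a constant image) become 0 with a logged warning;
  NGTDM coarseness on a constant image is capped at 10⁶.

## Group statistics

Each feature is compared between classes with a two-sided test chosen per
feature: Student's t-test with pooled variance if both class samples pass
Shapiro–Wilk at p > 0.05, Mann–Whitney U otherwise. The pooled-variance
form is the default (a Welch option exists). Significance stars follow the
strict-upper-bound convention applied from the smallest threshold upward.
No multiple-testing correction is applied by default, matching common
radiomics reporting practice; Benjamini–Hochberg is available. Samples in
which every observation is identical are reported as `p = 1` — the
Shapiro–Wilk and rank machinery are both degenerate there, and "no
evidence of difference" is the only defensible answer.

## Selection and classification

Standardization uses mean and sample SD learned from a fitting table;
constant features are flagged and mapped to zero. Selection fits a
100-tree random forest (seed 42) and keeps the 25 features with the
largest mean Gini impurity decrease, importances normalized to sum to 1;
ties at the k-th rank break by column order after a seeded shuffle that is
recorded in the result.

The three classifiers run with fixed hyperparameters (kNN k = 7 Euclidean
uniform; SVM RBF C = 100, γ = 10⁻⁴, tolerance 10⁻³; logistic regression
with L2 penalty, inverse strength C = 1, intercept unpenalized, fitted by
BFGS with a convergence tolerance tighter than the configured stopping
tolerance so results are reproducible to machine precision). The positive
class is the irregular (squamous-like) class; kNN scores are
neighbour-vote fractions, SVM scores oriented decision values, logistic
scores probabilities. AUC is computed by pair counting with half-credit
ties, which equals trapezoidal integration over thresholds.

**Cross-validation** is patient-grouped and stratified: per class,
patients are shuffled by the seed and dealt round-robin into folds, so no
patient's images ever span folds and per-class patient counts differ by at
most one. In the default leakage-safe mode, standardization *and*
selection are refitted inside every training fold. `mode = "paper"`
instead fits both once on the full table before splitting — the order in
which a protocol description typically lists the steps — and is provided,
labeled, because published pipelines are often ambiguous on this point.
The test suite demonstrates the difference operationally: with duplicated
images, an image-level split inflates nearest-neighbour accuracy while the
grouped split does not.

## The synthetic cohort

The generator emulates the *statistical shape* of a two-class patient
study: `n` patients per class (default 12 vs 19, mirroring a realistic
subtype imbalance), several ROIs per patient, 8-bit grayscale on disk
(PNG; lossless and readable everywhere — no BMP codec ships with the R
stack, and the pipeline treats the on-disk format as an interchange
detail).

* **Regular class**: white noise convolved with an isotropic Gaussian
  kernel (`corr_len_regular`, default 16 px under the `strong` preset),
  renormalized to exact unit marginal variance and mapped so ±3 SD spans
  the intensity range. With `corr_len` of the order of the image size the
  whole field collapses toward a constant — the smoothing limit.
* **Irregular class**: i.i.d. Gaussian noise (`noise_sd_irregular`,
  default 11) over a weak smooth background (amplitude 32, width 10).
  The background plays two roles: it gives the image enough spatial
  structure that the tolerance `r = 0.2 × SD` stays large relative to the
  noise (keeping sample-entropy matches defined), while the noise keeps
  every scale rougher than the regular class.
* **Patient structure**: every image is `0.5 × latent + 0.5 × own field`,
  where the latent field is drawn once per patient; in addition each
  patient draws one multiplicative jitter factor per texture parameter
  (`patient_jitter = 0.25`). The latent field makes images of a patient
  correlated (so image-level splits leak); the parameter jitter makes
  patients differ in texture *statistics*, which is what gives per-patient
  intraclass correlation in entropy features — a latent field alone
  changes the realization but not the statistics of i.i.d. noise.
* **Noise injection**: Gaussian (SD 2) plus salt-and-pepper (1% of pixels
  to min/max) in both classes, so the normalize and median filtrations
  have real work to do. The median filter demonstrably removes the
  salt-and-pepper component.
* **Presets**: `strong` (classes separable at every scale), `weak`
  (reduced contrast: noise SD 4, heavier injected noise), `null` (both
  classes drawn from the regular model with identical parameters — any
  detected difference is a false positive). The preset parameters were
  calibrated once against the ordering requirement (irregular above
  regular in mean SampEn2D/FuzzEn2D/DispEn2D at all five scales, with
  defined values) and then frozen.

What the generator does **not** emulate: MRI acquisition physics, partial
volume and bias fields, anatomical structure, inter-scanner variation, or
any PET signal. Passing tests on synthetic cohorts validates the
*software* — the statistics, the leakage-safety of the splitter, the
direction of the entropy contrasts — not the clinical claim that real ADC
and SCC tumors separate; that requires real images.

## Determinism

Every random draw derives from configuration seeds: the generator maps
(seed, patient, image) deterministically to per-image seeds kept inside
the 32-bit integer range; selection seeds the tie-breaking shuffle and the
forest together; the CV shuffle has its own seed (default 42, the one
fixed seed convention of the protocol). Two runs with one configuration
produce byte-identical feature CSVs and identical cross-validation
reports, which the acceptance suite asserts.

## Known limitations

* SampEn2D on strongly noisy input at coarse scales is undefined by
  construction; the imputed zeros are flagged, but users aggregating
  scale-4/5 sample entropy on small ROIs should expect this.
* The GLCM/GLRLM/GLSZM feature name lists follow the standard radiomics
  set of the right sizes; other implementations differ in a few formula
  details (e.g. difference-variance conventions), so cross-package
  numerical comparison requires care.
* The exhaustive pairwise entropies are O(n²) in the window count —
  quadratic work in the pixel count squared. The compiled kernels handle
  128×128 in seconds; whole-slide inputs are out of scope.
* `mode = "paper"` is intentionally leakage-prone (selection sees the test
  patients' features); it exists for comparability, not for reporting.
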