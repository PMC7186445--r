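---
title: "Dose and electron-density radiomics for late fibrosis risk: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose and electron-density radiomics for late fibrosis risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bedomics)
```

## The problem and the modelling idea

Late subcutaneous fibrosis is a dose-dependent toxicity of breast
radiotherapy. Classical normal-tissue complication models summarize the dose
distribution by a dose-volume histogram; the approach implemented here
instead treats the 3D dose distribution and the planning CT as *images* and
asks whether their spatial texture carries additional predictive signal.

Two normalizations make texture comparable across patients:

* **HU → RED.** Hounsfield units depend on the scanner's calibration, so CT
  volumes are mapped to electron density relative to water through a
  measured piecewise-linear calibration curve (`hu_to_red()`). Beyond the
  tabulated range the terminal segment is continued linearly and clamped at
  zero — electron density cannot be negative, and clamping is preferable to
  refusing out-of-range voxels (metal artifacts, air).
* **Dose → BED.** Patients are treated with different hypofractionation
  schemes. Each voxel receiving total dose \(D\) in \(n\) fractions is
  converted with the linear-quadratic model,
  \(\mathrm{BED} = D\,(1 + \tfrac{D/n}{\alpha/\beta})\), using the
  patient's fraction number and \(\alpha/\beta = 3\) Gy (late-responding
  subcutaneous tissue). The per-voxel fraction size \(d = D/n\) is the
  standard reading when only the fraction count is known. The three
  supported schemes (40 Gy/10, 35 Gy/7, 28 Gy/4) are deliberately
  iso-effective: all give a prescription-point BED of 93.33 Gy, which the
  test suite verifies in closed form.

## Feature extraction

All volumes are resampled to a common 3 mm isotropic grid (trilinear for
continuous volumes, nearest-neighbour for masks — the mask invariant "output
is binary" is enforced structurally). Intensities inside each ROI are
discretized into **64 equally spaced bins** over the in-ROI `[min, max]`
(fixed-bin-number scheme); filtered image versions are re-discretized over
their own range, the IBSI-consistent choice when the filter changes the
intensity scale.

The catalog (`feature_catalog()`) has 954 columns:

* **21 shape features** per ROI (breast, PTV), computed once per ROI from
  the mask. The mesh surface underlying sphericity and its derivatives is a
  marching-tetrahedra isosurface at 0.5 computed on a copy of the mask
  smoothed with a 0.6-voxel Gaussian. The smoothing removes voxelization
  jaggedness: on binary data every isosurface vertex sits at an edge
  midpoint and a digital sphere's area is overestimated by ~28%, while with
  light smoothing digital spheres of radius 4–15 voxels recover analytic
  areas to a few percent (sphericity 0.96–1.02). The sigma was fixed by
  that sphere calibration and is not exposed as a tuning knob. Masks too
  thin to survive smoothing (e.g. a single voxel) fall back to the exact
  voxel-face area.
* **57 intensity features** — 18 first-order, 25 GLCM, 14 GLRLM — per
  combination of image (RED, BED), ROI (breast, PTV) and filter (none,
  Gaussian σ = 3 mm, Laplacian-of-Gaussian σ = 3 mm, 3×3×3 median):
  `21·2 + 57·2·2·4 = 954`. The 57-feature split is a package decision (the
  constituent list is not published); it uses the full 25-feature IBSI GLCM
  set and drops two GLRLM features (gray-level non-uniformity normalized,
  run entropy) from the 16-feature IBSI set, and is guaranteed to contain
  every feature the reference signature names (cluster shade, RLN,
  kurtosis, range, 10th percentile, inverse variance, variance).

GLCM matrices pair voxels at distance 1 over the 13 unique 3D directions,
symmetrized and merged into a single matrix before normalization; GLRLM
runs are extracted per direction with ROI exit breaking a run, and counts
are summed over directions. Both are validated against brute-force pair and
run enumeration to 1e-10 on random grids. Kurtosis uses the excess
convention; degenerate (zero-variance) ROIs return flagged zeros rather
than NaN so selection never crashes.

## Class imbalance: ADASYN

`adasyn()` implements adaptive synthetic sampling from its definition: with
minority deficit \(G = \beta\,(n_{maj}-n_{min})\), each minority point
\(i\) receives \(g_i = \mathrm{round}(\hat r_i G)\) synthetic points where
\(\hat r_i\) normalizes \(r_i = \Delta_i/k\), the fraction of majority
points among its \(k = 5\) nearest neighbours (all classes). Each synthetic
point is \(x_i + \lambda (x_z - x_i)\), \(\lambda \sim U(0,1)\), with
\(x_z\) drawn from the \(k\) nearest *minority* neighbours. Distances are
Euclidean on z-scored features (radiomics features span ~9 orders of
magnitude; unstandardized distances would be dominated by cluster shade);
synthesis happens in original units. Per-instance round-half-up allocation
leaves a few rows of slack around the exact deficit, so a 124/41 table
balances to 50% within about one percentage point rather than exactly —
the behaviour expected of this allocation rule.

## Selection, training and the leakage question

**Selection** is wrapper-style forward stepwise: candidates are compared by
the mean out-of-fold binomial deviance of a logistic GLM under a seeded
stratified 5-fold split held fixed across candidates within a step (paired
comparison, which removes fold noise from the comparison). Ties break
lexicographically; non-converging fits get an infinite criterion.

**Trainers** share one harness (`tune_by_cv`): candidates are compared by
5-fold cross-validated *balanced* error (mean of the two class-conditional
error rates — identical to plain misclassification on the balanced
augmented design, but a constant classifier can never score below 0.5 on
imbalanced validation rows). The SVM searches a log grid for the box
constraint and RBF kernel scale; the ensemble runs a seeded random search
over {random forest, AdaBoost, LogitBoost, GentleBoost, RUSBoost} ×
(cycles, learning rate, minimum leaf size) with rpart trees (depth ≤ 3) as
weak learners; naive Bayes chooses between Gaussian and kernel densities
with a searched bandwidth multiplier. All three are deterministic given
(table, features, seed, budget).

**Leakage.** The reference procedure augments the dataset once and
cross-validates on the augmented rows. Because every synthetic row is a
convex combination of two real minority rows, its "twins" land in training
folds when it is held out, which inflates apparent performance — the
package reproduces this protocol as `leakage_mode = "augment_first"` and verifies
the inflation direction in a test. The default for method development is
`"safe"`: outer folds are drawn on original rows only, and augmentation
happens *inside* the trainer via an `augment` hook, so hyperparameter
selection also folds original rows and augments only its inner training
folds (nested re-augmentation). This matters in practice: selecting SVM
hyperparameters by CV on an already-augmented table picks memorizing
configurations (large C, large γ) whose honest out-of-fold AUC is ~0.15
below a logistic baseline, while nested re-augmentation recovers it.

**Evaluation** pools out-of-fold predictions per repeat (stabler than
per-fold averaging at n ≈ 250) and reports means with empirical 2.5/97.5
percentile intervals over repeats; the CI method is a package choice. The
acceptance gate (`model_gate()`) requires mean sensitivity ≥ 0.75,
specificity ≥ 0.75, AUC ≥ 0.85, all with ≥ semantics, plus a passed
monotonicity verdict when one is supplied.

**Monotonicity vetting** evaluates the model score on a 100-point grid over
the observed range of a BED feature with the other selected features fixed
at a profile (cohort means by default; the averages of extreme-score
subsets from `extreme_patients()` reproduce the published-figure style).
The verdict tolerates decreases up to `1e-6` times the curve's score range
— strictly a numerical-noise guard, not a biological allowance. Increasing
dose must not predict decreasing risk; unimodal responses are the signature
of an overfit ensemble and are rejected.

## The synthetic cohort

`generate_phantom()` builds, deterministically per (seed, index): a
half-ellipsoid breast of air-surrounded tissue on a 48×48×32 grid at 2.5 mm
(a deliberate compromise — coarse enough that a full catalog extraction
takes ~2 s/patient, fine enough for nontrivial texture); HU as a
thresholded Gaussian-smoothed noise field giving spatially correlated
fat (−100 HU) / gland (+40 HU) texture with ~6 mm correlation FWHM and a
per-patient gland fraction in [0.2, 0.6]; a spherical PTV (radius 10–16 mm)
whose center must lie more than radius + 5 mm from every non-breast voxel
(the skin-margin constraint, checked exactly on the grid); dose as a
prescription plateau with logistic penumbra (5 mm scale, 95% coverage at
the PTV surface) and a Gaussian hot spot with configurable probability;
covariates drawn from the cohort-level frequencies of the emulated study.
Outcomes follow `Bernoulli(plogis(b0 + Σ coef · z))` on cohort-standardized
planted features, with the intercept calibrated by root-finding so the
expected prevalence matches the configured 24.8%.

Default planted effects sit on the BED-PTV 10th percentile (+) and RED-PTV
kurtosis (−), the directions the emulated findings report. The "strong"
scenario used in the planted-recovery tests sets (1.5, −1.2), i.e. a latent
SD of ~1.9 and a Bayes-optimal AUC of ~0.86 — matching the discriminability
scale of the reference results, so the tests measure how much of an
attainable signal the pipeline retains. What the phantoms do *not* emulate:
anatomical realism (no ribs, skin line as a hard cutoff), scanner-specific
noise spectra, dose calculation physics (the penumbra is radial, not
beam-shaped), and any real correlation structure between the 954 features —
so passing tests demonstrate pipeline correctness and statistical
calibration, not clinical performance on real cohorts.

`generate_cohort_features()` is the feature-space shortcut (independent
normal features, same outcome model) used where image-level phantoms would
only add runtime: selection-recovery and CV-calibration experiments.

## Problem sizes and numerical choices

The shipped tests run at deliberately desk-scale sizes: 5×5×5 grids for the
texture oracles (50 instances per family), one full-catalog patient for the
954-column identity, n = 300 feature-level cohorts with 10–25 seeds or
repeats for selection recovery and CV calibration, and 500-repeat CV is
scaled to 10–50 repeats (the CI-narrowing property is checked rather than
the headline width). Null-calibration is judged on the mean over five
independent cohorts because a single cohort's CV AUC is a draw with
SE ≈ 0.04 at n = 300.

Other numerical decisions: voxel-center coordinate convention with 0-based
physical origins; masks rasterized by center-inclusion (even-odd rule);
trilinear/nearest interpolators fixed; filters operate in physical units
(σ in mm converted per-axis to voxels) with edge replication; percentiles
by linear interpolation (type 7); the GLM deviance is clamped at
probabilities 1e-12 from the boundary; SVM decision values are re-oriented
so positives score higher (libsvm's sign depends on class order); the
median filter is exact (sorted neighbourhood), not an approximation.

## Known limitations

* RTSTRUCT files are not parsed; contours enter as per-slice polygon lists
  or mask volumes. CT and RTDOSE reading supports explicit-VR little-endian
  DICOM only.
* The 57-feature split is one defensible reading of an unpublished list;
  other splits reproduce the same total.
* ADASYN's exact augmented-row count is not enforced (only ≈50% balance),
  matching the allocation rule's intrinsic rounding slack.
* Clinical covariates are carried and tested univariately but are appended
  outside the 954 image-feature catalog.
* The augment-first evaluation mode is reproduced for comparability but is
  optimistic by construction; conclusions about real predictive value
  should rest on safe mode.
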