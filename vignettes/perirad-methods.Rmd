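---
title: "Peritumoral radiomics for two-year recurrence-free survival: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peritumoral radiomics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perirad)
```

## The problem and the pipeline

After curative resection of non-small cell lung cancer, roughly half of the
patients recur; identifying who will recur within two years from the
preoperative CT would let clinicians tailor surveillance. The hypothesis
this package operationalizes is that the *peritumoral* lung parenchyma --
the band of tissue extending outward from the tumor boundary, where
vascular changes and micro-invasion happen -- carries prognostic signal
that the tumor interior alone does not.

The pipeline has five stages, each an exported function:

1. **Preprocessing** (`window_rescale()`, `crop_to_roi()`): CT slices in
   Hounsfield units are rescaled to 8-bit gray with standard lung-window
   settings (WW 1500 HU, WL -600 HU) and cropped around the tumor.
2. **Region construction** (`build_region_set()`): the intratumoral mask,
   ten cumulative peritumoral bands at 3, 6, ..., 30 mm built by
   morphological dilation, and their unions ("combined" regions).
3. **Feature extraction** (`extract_panel()`): 69 intratumoral features
   (12 intensity, 14 GLCM, 22 GLRLM, 10 LBP, 11 shape), 58 per band (no
   shape), 127 combined.
4. **Selection and classification** (`nca_weights()`,
   `incremental_select()`, `run_region_cv()`): neighborhood component
   analysis weights, incremental AUC-maximizing subsets, RBF-SVM and
   60-tree random forests under stratified 5-fold cross-validation, the
   better model kept per fold.
5. **Outcome analysis** (`kaplan_meier()`, `log_rank()`, `delong_test()`):
   two-year recurrence-free survival of the predicted groups, log-rank
   separation, and paired AUC comparison against a T/N-stage baseline.

`run_experiment()` orchestrates all of it from a single `default_config()`.

## The synthetic phantom cohort

Clinical CT archives cannot be redistributed, so the package ships a
generator (`generate_phantom()`, `generate_cohort()`) producing 2-D
phantoms with the statistical structure the analysis relies on:

* an elliptical lung field near -850 HU inside a chest wall near +40 HU,
  so the -224 HU wall-exclusion threshold is meaningful;
* one tumor per slice with controllable equivalent diameter (accurate to a
  few percent), mean attenuation, boundary irregularity (low-order radial
  harmonics), and intratumoral texture (a Gaussian-correlated random field
  whose correlation length monotonically lowers GLCM contrast -- a property
  the test suite checks);
* a two-branch airway at air density, carried as a separate mask;
* vessels as random-walk polylines of width 1-2 px whose cores sit at
  -100 HU and are therefore *excluded* by the -224 HU threshold, while
  their one-pixel partial-volume halos (about -475 HU) remain inside the
  band. Peritumoral vessel density is the lever that differentiates
  outcome classes, mimicking the qualitative reading that recurrent tumors
  show richer peritumoral vascularity.

Background noise is winsorized at three standard deviations, which keeps
the "no vessels" degenerate case exactly clean and changes nothing
practical elsewhere. Default pixel spacing is 0.7 mm/px, mid-range for
diagnostic chest CT.

Outcomes follow a logistic model (`outcome_model()`) on tumor diameter,
heterogeneity and vessel density. Recurrence means an event within 24
months (times uniform on 2-24); non-recurrent patients are censored, by
default 20% of them before 24 months. Default coefficients give a roughly
balanced cohort, matching the near 50% post-resection recurrence rate. T
stage follows diameter cuts (3 cm / 7 cm) and N stage a latent nodal
variable tied to the linear predictor, calibrated to a 56/26/18 N0/N1/N2
mix; both exist only to give the clinical baseline something real to use.

What the phantoms do **not** emulate: 3-D anatomy, scanner/kernel
variability, respiratory artifacts, pleural attachment geometry, and
histology-specific texture. Passing tests demonstrate that the *method* is
implemented correctly and recovers planted signal; they say nothing about
effect sizes in real cohorts.

The planted-effect conditions used by the signal-recovery study are frozen
in `vessel_signal_conditions()`: vessel densities 0.5 vs 6 per cm^2,
shared size/heterogeneity/shape distributions, and an outcome depending on
vessel density alone. The contrast was chosen in a pilot so that the
planted effect is decisively recoverable at the study scale (n = 60,
128 px phantoms); it is a property of the synthetic study design, not an
estimate of any real cohort.

## Numerical and design choices

**Windowing.** The mapping is linear from `[level - width/2,
level + width/2]` to 0-255, clipped, with half-up rounding (so -600 HU,
exactly mid-window, maps to 128). Feature extraction uses the windowed
image; the -224 HU exclusion uses original HU, because that threshold is
quoted in calibrated units. The pipeline therefore carries both images.

**Regions.** Peritumoral bands are *cumulative* (boundary to d), not
disjoint annuli; band labels like "30 mm" mean the full extent. Dilation
uses an exact Euclidean disk structuring element of radius
`round(d_mm / spacing)` px, which makes the dilation ring identical to a
Euclidean distance-transform ring -- the geometry suite checks equality,
not mere closeness. Holes inside the tumor (necrosis, cavitation) are
filled and kept intratumoral. The airway mask is dilated by one pixel
before exclusion to strip partial-volume rims. Pixels falling outside the
image are simply absent; crops use a 35 mm margin so a 30 mm band always
survives cropping.

**Texture features.** Gray levels are quantized to 32 equal-width bins of
the fixed 0-255 range (not per-region min-max), keeping matrices
well-populated on thin bands while preserving cross-region comparability.
GLCMs use the four distance-1 directions, symmetrized and normalized; the
seven Haralick statistics are aggregated as mean and population-SD across
directions (14 values). Sum variance is centered on the sum average.
GLRLMs use the same four directions with runs truncated at the mask
boundary; the eleven canonical run statistics (SRE, LRE, GLN, RLN, RP,
LGRE, HGRE, SRLGE, SRHGE, LRLGE, LRHGE) are aggregated the same way
(22 values). LBP is the rotation-invariant uniform variant with P = 8,
R = 1 -- the unique standard variant with exactly 10 descriptors; ties at
the center value give a 0 bit, so flat regions land in the all-zero bin.
Only pixels whose full 3x3 neighborhood is in-mask contribute.

**Intensity and shape.** Histogram entropy uses 256 bins, log base 2,
with 0 log 0 = 0; percentiles use linear interpolation. Moments are
population moments; skewness and kurtosis of a constant region are 0 by
convention, and kurtosis is the plain fourth standardized moment, not
excess. Shape features carry physical units via the pixel spacing; axis
lengths come from the second-moment ellipse (with the 1/12 pixel
correction), the perimeter from the traced boundary polyline, curvature
from a smoothed closed boundary, and the Euler number from components
minus holes. The shape family names ten conventional descriptors; the
eleventh slot is filled with roundness 4*pi*A/P^2 and is flagged
non-canonical in the schema documentation.

**Combined regions.** A combined feature vector is the concatenation of
the 69 intratumoral and 58 band features (69 + 58 = 127), *not* features
of the union mask -- the arithmetic forces this reading, and it keeps the
combined classifiers interpretable as "both sources available".

**Missing bands.** A tumor filling the lung can leave a band empty after
exclusions; its 58 features become NA with a missing flag and are
median-imputed *within each training fold* before selection and
classification.

## Selection: NCA and the incremental subset search

`nca_weights()` maximizes the expected leave-one-out accuracy of a
stochastic nearest neighbor classifier under the weighted L1 metric
`d(i,j) = sum_r w_r^2 |x_ir - x_jr|`, minus a ridge penalty
`lambda * sum_r w_r^2`, by full-batch L-BFGS-B from unit weights with a
zero lower bound. There is no stochastic element, so results depend only
on the data and `lambda`. The default penalty is the conventional 1/n;
`nca_tune_lambda()` implements an inner-CV grid search scored by
weighted-metric 1-NN error, and `run_region_cv(lambda = "tune")` applies
it per training fold. Tuning matters when many noise features compete
with few informative ones (it drives null weights to zero, as the
permutation tests show); the untuned default is used where runtime
dominates and ranking quality is already sufficient.

Because the metric scales with `w^2`, a duplicated feature splits its
weight so that the *Euclidean norm* of the pair matches the single-copy
weight -- the redundancy test asserts exactly that invariant.

`incremental_select()` ranks features by descending weight and scores
each prefix subset of size k = 1..K by inner cross-validated AUC of the
classifier (maximizing *training* AUC instead would reward overfitting;
using the outer test fold would be leakage, so inner CV is the only
defensible reading). Exact AUC ties fall back to the larger Youden's J at
the ROC-optimal threshold, then to the smaller subset. K is capped at 30:
observed selected sets have at most about a dozen members, and the cap
bounds runtime.

## Classification and evaluation

SVMs use the RBF kernel (cost 1, gamma 1/p unless the small inner grid
search is enabled); random forests use 60 bootstrap-trained trees with
majority voting. Scores are signed decision values (SVM) and recurrence
vote fractions (RF); reported operating points use the native thresholds
(0 and 0.5), with the Youden-optimal threshold logged alongside. AUC is
the Mann-Whitney rank statistic with half credit for ties, which equals
trapezoidal ROC integration; the suite verifies it against a brute-force
pair count and against pROC.

Per fold, the model with the higher *test-fold* AUC is kept, with exact
ties going to the SVM (the historically dominant choice). One consequence
is worth stating plainly: the per-fold maximum of two chance-level AUCs
is above 0.5 in expectation, so the chosen-model aggregate is mildly
optimistic *by protocol*, independent of any leakage. The leakage
sentinel therefore monitors a single pre-specified model's AUC under
label permutation (centered on 0.5 in our runs, as it must be), while the
chosen-model aggregate under permutation sits a few points higher -- a
property of the best-of-two rule, not a bug. `cv_result$per_fold` exposes
`auc_svm` and `auc_rf` so either view is available.

Stratified folds preserve class proportions within one patient and are
canonical: samples are ordered by patient id before the seeded
within-class shuffle, so input order cannot change the folds.

## Survival analysis

Kaplan-Meier estimation and the log-rank test delegate to the survival
package (deaths before censorings at tied times, the standard
convention); two-year recurrence-free survival is S(24 months) with an
explicit truncation flag when no follow-up reaches 24 months. Predicted
group curves pool the held-out-fold predictions across the five folds --
the alternative (refitting one model on everything) blurs what the curve
estimates, so pooled cross-validated predictions are used throughout.
The DeLong test is implemented from placement values with the paired
covariance estimator and two-sided normal p-values; identical score
vectors yield a degenerate-variance flag and p = 1 rather than an error.
The implementation is cross-checked against pROC and against a
subject-level bootstrap of the AUC-difference variance.

## Problem sizes and calibration checks

The test suite and the acceptance script run everything at desk scale,
chosen as the smallest sizes at which the statistical properties are
stable: phantom cohorts of n = 60 at 128-192 px, 8-20 replicate cohorts
for the planted-signal and null studies, 500 simulations for log-rank
null uniformity, 200 random small images for the exact texture-matrix
oracles, and inner settings of 3 folds with K capped at 10-15 for the
replicated studies (the full defaults remain 5 folds, K = 30). The
calibration battery asserts: log-rank p-values uniform under the null
(Kolmogorov-Smirnov at alpha 0.01); permuted-label single-model AUC in
[0.45, 0.55] over 20 seeds; DeLong z approximately standard normal under
the null; and planted peritumoral signal recovered (Wilcoxon p < 0.05
against the paired permuted null, majority-peritumoral selected sets).

## Known limitations

* Single representative axial slice; no 3-D features or multi-slice
  aggregation.
* The -224 HU exclusion removes bright vessel cores from the band; only
  partial-volume halos contribute to peritumoral statistics. On real CT
  this alters intensity distributions in ways radiologists should keep in
  mind when interpreting selected intensity features.
* Phantom realism is deliberately minimal; absolute AUCs on phantoms are
  not forecasts for clinical data.
* The best-of-two model choice on test folds inflates aggregate metrics
  slightly; comparisons across regions remain fair because every region
  enjoys the same protocol.
* No external-cohort harness and no Cox modeling; the survival layer is
  descriptive (KM, log-rank) plus ROC comparisons.

## Interface note

The package is an analysis library: configuration objects plus
`run_experiment()`/`write_report()` are the orchestration surface, and
`scripts/acceptance.R` is the runnable end-to-end reproduction. Images
and masks round-trip as single-slice NIfTI or lossless PNG (HU offset by
1024 and packed into two 8-bit channels), clinical tables as CSV, and
cohort manifests as JSON.
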