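# perirad

Intra- and peritumoral CT radiomics for predicting two-year
recurrence-free survival (RFS) in resected non-small cell lung cancer.

About half of operable NSCLC patients recur after surgery. Beyond tumor
size and nodal stage, the lung parenchyma *around* the tumor — where
vascular remodeling and microscopic invasion occur — may carry prognostic
signal invisible to the eye. `perirad` implements a complete, tested
pipeline for interrogating that hypothesis on single axial CT slices, plus
a synthetic CT-phantom cohort generator so every stage runs and is
validated without any clinical data.

## What it computes

* **Regions.** From a tumor mask: the intratumoral region (cavities
  filled), cumulative peritumoral bands at d = 3, 6, …, 30 mm built by
  morphological dilation with an exact Euclidean disk of radius
  round(d/spacing) px, excluding chest wall/mediastinum by the −224 HU
  threshold and the bronchi via a supplied airway mask, and combined
  regions (intratumoral ∪ band).
* **Features.** On the lung-windowed image (WW 1500 / WL −600 HU, 0–255):
  69 intratumoral features = 12 intensity (7 histogram statistics + 5
  percentiles) + 14 GLCM (7 Haralick statistics × mean/SD over 4
  directions) + 22 GLRLM (11 run statistics × mean/SD) + 10 uniform LBP
  (P = 8, R = 1) + 11 shape; 58 per peritumoral band (no shape); 127
  combined (69 + 58, by concatenation).
* **Selection.** Neighborhood component analysis (NCA) feature weights —
  maximizing leave-one-out stochastic-nearest-neighbor accuracy under the
  weighted metric d(i,j) = Σᵣ wᵣ² |xᵢᵣ − xⱼᵣ| with an L2 penalty — then an
  incremental search over top-k prefixes scored by inner-CV AUC, ties
  broken by Youden's J, then by smaller k.
* **Classification.** RBF-kernel SVM and 60-tree random forest under
  stratified 5-fold cross-validation; per fold the better model (by test
  AUC, ties → SVM) is kept; ACC/SEN/SPEC/PPV/NPV and Mann–Whitney AUC are
  reported, plus a T/N-stage clinical baseline and tumor-size subgroup
  analyses (<3 cm, 3–5 cm, ≥5 cm).
* **Survival.** Kaplan–Meier curves of the predicted groups from pooled
  held-out predictions, S(24 months) as the two-year RFS, log-rank tests,
  and paired DeLong comparisons of correlated AUCs.

## Worked example: recovering planted peritumoral signal

`vessel_signal_conditions()` defines a synthetic study in which the two
outcome classes differ *only* in peritumoral vessel density — tumor size,
texture and shape are exchangeable — so any predictive signal must live in
the peritumoral band:

```r
library(perirad)

cond <- vessel_signal_conditions()
co <- generate_cohort(60, class_specs = cond$class_specs,
                      outcome = cond$outcome, seed = 1001,
                      diameter_meanlog = cond$diameter_meanlog,
                      diameter_sdlog = cond$diameter_sdlog,
                      diameter_range = cond$diameter_range)
ft <- extract_feature_table(co$images, distances_mm = 30)
y  <- co$records$recurrence

res_peri  <- run_region_cv(region_design_matrix(ft, "peri_30"), y,
                           seed = 1, inner_folds = 3, K_cap = 10,
                           ids = co$records$patient_id)
res_intra <- run_region_cv(region_design_matrix(ft, "intra"), y,
                           seed = 1, inner_folds = 3, K_cap = 10,
                           ids = co$records$patient_id)
res_peri
#> <cv_result> 5 folds | ACC 86.9 SEN 87.6 SPEC 86.0 AUC 0.891 | models: rf,svm,svm,svm,svm
res_intra
#> <cv_result> 5 folds | ACC 54.3 SEN 52.9 SPEC 56.0 AUC 0.599 | models: svm,svm,svm,rf,rf

res_peri$selected[[1]]
#> [1] "peri_30__hist_p50"     "peri_30__glrlm_rp_std" "peri_30__hist_p25"

sv <- predicted_group_survival(co$records, res_peri$pooled)
sprintf("two-year RFS | predicted recurrence: %.2f | non-recurrence: %.2f",
        sv$rfs24_pred_rec, sv$rfs24_pred_nonrec)
#> [1] "two-year RFS | predicted recurrence: 0.12 | non-recurrence: 0.84"
sv$test
#> <log-rank> statistic = 29.72, p = 5.003e-08
```

Reading the numbers: cross-validated peritumoral features classify
recurrence with AUC 0.89 while intratumoral features hover near chance
(0.60) — as designed, since only the band carries signal — and the
predicted groups' recurrence-free survival curves separate sharply (12%
vs 84% event-free at two years, log-rank p ≈ 5×10⁻⁸). The selected
features are peritumoral intensity percentiles and run-length statistics,
i.e. exactly the descriptors vessel halos perturb.

The full multi-region experiment (all 21 region tags, clinical baseline,
DeLong comparisons, size subgroups) runs from one config:

```r
bundle <- run_experiment(default_config(n_patients = 60, seed = 7))
bundle$metrics          # one row per region tag + clinical baseline
write_report(bundle, "out/")  # CSVs, KM curves, JSON summary
```

## Layout

| Path | Contents |
| --- | --- |
| `R/phantom.R` | phantom specs, cohort generator, outcome model |
| `R/preprocess.R` | lung windowing, ROI cropping |
| `R/regions.R` | intratumoral / peritumoral / combined masks |
| `R/features-*.R` | intensity, GLCM, GLRLM, LBP, shape panels |
| `R/selection.R` | NCA weights, λ tuning, incremental subset search |
| `R/classify.R` | folds, SVM/RF, metrics, subgroup analysis |
| `R/survival.R` | KM, log-rank, DeLong, predicted-group curves |
| `R/pipeline.R`, `R/io.R` | orchestration, config, NIfTI/PNG/CSV/JSON |
| `vignettes/perirad-methods.Rmd` | model, assumptions, design decisions |
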