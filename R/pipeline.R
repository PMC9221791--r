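#' Default experiment configuration
#'
#' All analysis defaults are the study-standard values: lung window
#' WW 1500 / WL -600 HU, peritumoral bands 3-30 mm in 3 mm steps, -224 HU
#' chest-wall exclusion, 32 gray levels for texture matrices, 60-tree
#' random forests, stratified 5-fold cross-validation, and 3 cm / 5 cm
#' tumor-size group boundaries. Cohort settings control the synthetic
#' phantom generator only.
#'
#' @param n_patients synthetic cohort size.
#' @param distances_mm peritumoral band extents.
#' @param region_tags region tags to evaluate; `NULL` means the intratumoral
#'   region plus every peritumoral and combined band.
#' @param seed master seed.
#' @param ... overrides for nested entries (`window`, `crop_margin_mm`,
#'   `threshold`, `cv_folds`, `inner_folds`, `K_cap`, `lambda`,
#'   `n_trees`, `tune_svm`, `size_groups`, `image_size`, `class_specs`,
#'   `outcome`).
#' @return list of class `run_config`.
#' @export
default_config <- function(n_patients = 60L,
                           distances_mm = seq(3, 30, by = 3),
                           region_tags = NULL, seed = 1L, ...) {
  cfg <- list(
    n_patients = n_patients,
    image_size = 192L,
    class_specs = NULL,        # filled with default_class_specs(image_size)
    outcome = outcome_model(),
    diameter_meanlog = log(30),
    diameter_sdlog = 0.45,
    diameter_range = c(10, 85),
    window = c(width = 1500, level = -600),
    crop_margin_mm = 35,
    distances_mm = distances_mm,
    threshold = -224,
    quantization_levels = 32L,
    cv_folds = 5L,
    inner_folds = 5L,
    K_cap = 30L,
    lambda = NULL,
    n_trees = 60L,
    tune_svm = FALSE,
    size_groups = c(3, 5),
    run_size_groups = FALSE,
    region_tags = region_tags,
    seed = as.integer(seed)
  )
  over <- list(...)
  cfg[names(over)] <- over
  if (is.null(cfg$class_specs)) {
    cfg$class_specs <- default_class_specs(image_size = cfg$image_size)
  }
  if (is.null(cfg$region_tags)) {
    cfg$region_tags <- c("intra", paste0("peri_", cfg$distances_mm),
                         paste0("comb_", cfg$distances_mm))
  }
  class(cfg) <- "run_config"
  cfg
}

#' Filter a clinical cohort by exclusion rules
#'
#' Applies named exclusion predicates sequentially; each rule is a function
#' of the (remaining) records returning `TRUE` for patients to exclude.
#' Typical rules remove missing outcomes, missing stage, or oversized
#' tumors.
#'
#' @param records clinical data.frame.
#' @param rules named list of predicate functions.
#' @return list with `records` (kept rows) and `exclusions` (per-rule
#'   counts).
#' @export
filter_cohort <- function(records, rules = list()) {
  counts <- integer(length(rules))
  names(counts) <- names(rules)
  for (nm in names(rules)) {
    drop <- rules[[nm]](records)
    drop[is.na(drop)] <- TRUE
    counts[nm] <- sum(drop)
    records <- records[!drop, , drop = FALSE]
  }
  if (nrow(records) == 0) stop("all patients excluded")
  list(records = records, exclusions = counts)
}

#' Standard exclusion rules for clinical tables
#'
#' Missing recurrence outcome, missing T or N stage, and tumors larger
#' than `max_diameter_cm` (19 cm by default, removing implausible
#' segmentations and extreme outliers).
#'
#' @param max_diameter_cm oversize exclusion boundary.
#' @return named list of predicates for [filter_cohort()].
#' @export
standard_exclusion_rules <- function(max_diameter_cm = 19) {
  list(
    missing_outcome = function(r) is.na(r$recurrence) | is.na(r$time_months),
    missing_stage = function(r) is.na(r$t_stage) | is.na(r$n_stage),
    oversize = function(r) r$tumor_longest_diameter > max_diameter_cm
  )
}

#' Run the end-to-end radiomics experiment
#'
#' Simulates (or accepts) a cohort, extracts the feature panel, evaluates
#' every requested region tag with selection + SVM/RF cross-validation,
#' evaluates the T/N-stage clinical baseline, compares each radiomic
#' classifier against the baseline with the DeLong test on pooled
#' cross-validated scores, and builds Kaplan-Meier curves of the predicted
#' groups. Deterministic given the config seed.
#'
#' @param config a [default_config()].
#' @param cohort optional pre-built cohort (list with `images`,
#'   `records`); when `NULL` one is simulated from the config.
#' @return list of class `report_bundle` with `records`, `feature_table`,
#'   `metrics` (one row per region tag), `cv` (per-tag `cv_result`s),
#'   `clinical_cv`, `delong_vs_clinical`, `survival`, `size_groups`,
#'   `config`.
#' @export
run_experiment <- function(config = default_config(), cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(cohort)) {
    cohort <- generate_cohort(config$n_patients,
                              class_specs = config$class_specs,
                              outcome = config$outcome,
                              seed = config$seed,
                              diameter_meanlog = config$diameter_meanlog,
                              diameter_sdlog = config$diameter_sdlog,
                              diameter_range = config$diameter_range)
  }
  records <- cohort$records
  ft <- extract_feature_table(cohort$images,
                              distances_mm = config$distances_mm,
                              window_width = config$window["width"],
                              window_level = config$window["level"],
                              crop_margin_mm = config$crop_margin_mm,
                              threshold = config$threshold)

  cv <- list()
  surv <- list()
  delong <- list()
  clinical_cv <- run_region_cv(clinical_design_matrix(records),
                               records$recurrence, k = config$cv_folds,
                               seed = config$seed, select = FALSE,
                               config = model_config(config$n_trees,
                                                     tune_svm = config$tune_svm,
                                                     seed = config$seed),
                               ids = records$patient_id)
  clin_scores <- clinical_cv$pooled$score[order(clinical_cv$pooled$index)]

  for (tag in config$region_tags) {
    X <- region_design_matrix(ft, tag)
    res <- run_region_cv(X, records$recurrence, k = config$cv_folds,
                         seed = config$seed,
                         inner_folds = config$inner_folds,
                         K_cap = config$K_cap, lambda = config$lambda,
                         config = model_config(config$n_trees,
                                               tune_svm = config$tune_svm,
                                               seed = config$seed),
                         ids = records$patient_id)
    cv[[tag]] <- res
    surv[[tag]] <- predicted_group_survival(records, res$pooled)
    tag_scores <- res$pooled$score[order(res$pooled$index)]
    delong[[tag]] <- delong_test(tag_scores, clin_scores,
                                 records$recurrence)
  }

  metrics <- do.call(rbind, lapply(names(cv), function(tag) {
    data.frame(region_tag = tag, t(cv[[tag]]$aggregate),
               logrank_p = if (!is.null(surv[[tag]]$test)) surv[[tag]]$test$p_value else NA_real_,
               delong_p_vs_clinical = delong[[tag]]$p_value,
               stringsAsFactors = FALSE)
  }))
  metrics <- rbind(metrics,
                   data.frame(region_tag = "clinical_tn",
                              t(clinical_cv$aggregate),
                              logrank_p = NA_real_,
                              delong_p_vs_clinical = NA_real_,
                              stringsAsFactors = FALSE))

  size_groups <- NULL
  if (isTRUE(config$run_size_groups)) {
    size_groups <- size_subgroup_analysis(
      records, ft, region_tags = config$region_tags,
      k = config$cv_folds, seed = config$seed,
      inner_folds = config$inner_folds, K_cap = config$K_cap,
      lambda = config$lambda,
      config = model_config(config$n_trees, tune_svm = config$tune_svm,
                            seed = config$seed))
  }

  structure(list(records = records, feature_table = ft, metrics = metrics,
                 cv = cv, clinical_cv = clinical_cv,
                 delong_vs_clinical = delong, survival = surv,
                 size_groups = size_groups, config = config),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> %d patients, %d region tags\n",
              nrow(x$records), length(x$cv)))
  print(x$metrics[, c("region_tag", "acc", "sen", "spec", "auc")],
        digits = 3)
  invisible(x)
}

#' Write report artifacts (CSV metrics, JSON summary, KM curves)
#'
#' @param bundle a [run_experiment()] result.
#' @param dir output directory.
#' @return invisibly, the files written.
#' @export
write_report <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  f <- file.path(dir, "metrics.csv")
  utils::write.csv(bundle$metrics, f, row.names = FALSE)
  files <- c(files, f)
  selected <- lapply(bundle$cv, function(r) r$selected)
  f <- file.path(dir, "selected_features.json")
  jsonlite::write_json(selected, f, auto_unbox = FALSE, pretty = TRUE)
  files <- c(files, f)
  for (tag in names(bundle$survival)) {
    sv <- bundle$survival[[tag]]
    if (is.null(sv$curve_pred_rec)) next
    f <- file.path(dir, paste0("km_", tag, ".csv"))
    df <- rbind(cbind(group = "pred_recurrence",
                      km_as_data_frame(sv$curve_pred_rec)),
                cbind(group = "pred_non_recurrence",
                      km_as_data_frame(sv$curve_pred_nonrec)))
    utils::write.csv(df, f, row.names = FALSE)
    files <- c(files, f)
  }
  summary <- list(
    n_patients = nrow(bundle$records),
    seed = bundle$config$seed,
    schema_hash = feature_schema()$hash,
    metrics = bundle$metrics
  )
  f <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, f, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  files <- c(files, f)
  invisible(files)
}
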