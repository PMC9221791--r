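#' Mann-Whitney AUC of continuous scores
#'
#' Area under the ROC curve via the rank (Mann-Whitney U) formulation,
#' equivalent to trapezoidal ROC integration; tied score pairs receive half
#' credit. Recurrence (label 1) is the positive class.
#'
#' @param scores continuous scores, higher = more positive.
#' @param labels binary 0/1 labels.
#' @return AUC in \[0, 1\], or `NA` (with a warning) if only one class is
#'   present.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    warning("AUC undefined: one class absent")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified fold assignment
#'
#' Assigns each sample to one of `k` folds so that class proportions are
#' preserved within one sample per fold. Assignment is deterministic given
#' the seed and independent of input order when `ids` are supplied (samples
#' are canonically sorted by id before the within-class shuffle).
#'
#' @param labels binary 0/1 labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @param ids optional identifiers used for canonical ordering.
#' @return integer vector of fold numbers (1..k), in input order.
#' @export
stratified_folds <- function(labels, k = 5L, seed = 1L, ids = NULL) {
  labels <- as.integer(labels)
  n <- length(labels)
  if (k >= n) stop("k must be smaller than the number of samples")
  tab <- table(labels)
  if (length(tab) < 2) stop("both classes must be present")
  if (min(tab) < k) stop("each class needs at least k members")
  canon <- if (is.null(ids)) seq_len(n) else order(ids)
  fold <- integer(n)
  with_seed(seed, {
    for (cl in names(tab)) {
      members <- canon[labels[canon] == as.integer(cl)]
      fold[members] <- sample(rep(seq_len(k), length.out = length(members)))
    }
  })
  fold
}

#' Classifier configuration
#'
#' @param n_trees random-forest size (default 60 trees, bootstrap sampling,
#'   majority vote).
#' @param svm_cost,svm_gamma RBF-SVM hyperparameters; `svm_gamma = NULL`
#'   uses 1/n_features.
#' @param tune_svm if `TRUE`, a small inner-CV grid over cost and gamma is
#'   searched per training fold.
#' @param seed RNG seed for the forest.
#' @return list of class `model_config`.
#' @export
model_config <- function(n_trees = 60L, svm_cost = 1, svm_gamma = NULL,
                         tune_svm = FALSE, seed = 1L) {
  structure(list(n_trees = as.integer(n_trees), svm_cost = svm_cost,
                 svm_gamma = svm_gamma, tune_svm = tune_svm,
                 seed = as.integer(seed)),
            class = "model_config")
}

#' RBF-SVM classifier factory
#'
#' Returns a `(X, y) -> model` closure around [e1071::svm()] with the RBF
#' kernel; the fitted object is scored with [predict_scores()] using signed
#' decision values oriented so larger means recurrence.
#'
#' @param cost,gamma SVM hyperparameters (`gamma = NULL`: 1/n_features).
#' @return factory function.
#' @export
svm_factory <- function(cost = 1, gamma = NULL) {
  function(X, y) {
    if (length(unique(y)) < 2) stop("single-class training data")
    g <- if (is.null(gamma)) 1 / ncol(X) else gamma
    fit <- e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
                      kernel = "radial", cost = cost, gamma = g,
                      scale = FALSE)
    structure(list(fit = fit, kind = "svm"), class = "perirad_model")
  }
}

#' Random-forest classifier factory
#'
#' 60 bootstrap-trained trees with majority voting by default; scores are
#' the fraction of trees voting for recurrence.
#'
#' @param n_trees forest size.
#' @param seed RNG seed for tree growing.
#' @return factory function.
#' @export
rf_factory <- function(n_trees = 60L, seed = 1L) {
  function(X, y) {
    if (length(unique(y)) < 2) stop("single-class training data")
    fit <- with_seed(seed, {
      randomForest::randomForest(x = X, y = factor(y, levels = c(0, 1)),
                                 ntree = n_trees)
    })
    structure(list(fit = fit, kind = "rf"), class = "perirad_model")
  }
}

#' Continuous recurrence scores from a fitted model
#'
#' SVM models yield signed decision values (0 is the native threshold); RF
#' models yield vote fractions (0.5 is the native threshold). Higher always
#' means recurrence.
#'
#' @param model a `perirad_model`.
#' @param X feature matrix to score.
#' @return numeric scores.
#' @export
predict_scores <- function(model, X) {
  stopifnot(inherits(model, "perirad_model"))
  if (model$kind == "svm") {
    pr <- stats::predict(model$fit, X, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # e1071 orients decision values toward the first label in the colname
    pos_first <- startsWith(colnames(dv)[1], "1")
    if (pos_first) as.numeric(dv[, 1]) else -as.numeric(dv[, 1])
  } else {
    votes <- stats::predict(model$fit, X, type = "vote")
    as.numeric(votes[, "1"])
  }
}

native_threshold <- function(kind) if (kind == "svm") 0 else 0.5

# small inner grid search for SVM (cost x gamma), scored by inner-CV AUC
tune_svm_grid <- function(X, y, seed = 1L) {
  p <- ncol(X)
  grid <- expand.grid(cost = c(0.5, 1, 4), gamma = c(0.5, 1, 2) / p)
  k <- min(3L, min(table(y)))
  if (k < 2) return(list(cost = 1, gamma = 1 / p))
  fold_id <- stratified_folds(y, k = k, seed = seed)
  aucs <- apply(grid, 1, function(g) {
    s_all <- numeric(0); y_all <- integer(0)
    for (f in seq_len(k)) {
      tr <- fold_id != f
      if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) next
      m <- svm_factory(g[["cost"]], g[["gamma"]])(X[tr, , drop = FALSE], y[tr])
      s_all <- c(s_all, predict_scores(m, X[!tr, , drop = FALSE]))
      y_all <- c(y_all, y[!tr])
    }
    if (length(s_all)) auc_score(s_all, y_all) else NA_real_
  })
  best <- which.max(aucs)
  list(cost = grid$cost[best], gamma = grid$gamma[best])
}

#' Train SVM and RF on a training split and score a test split
#'
#' @param X_train,y_train,X_test training data (already standardized and
#'   imputed) and test features.
#' @param config a [model_config()].
#' @return list with per-model `scores`, `pred` (at the native threshold)
#'   and `threshold`.
#' @export
train_and_score <- function(X_train, y_train, X_test,
                            config = model_config()) {
  if (length(unique(y_train)) < 2) stop("single-class training fold")
  svm_par <- list(cost = config$svm_cost, gamma = config$svm_gamma)
  if (isTRUE(config$tune_svm)) {
    svm_par <- tune_svm_grid(X_train, y_train, seed = config$seed)
  }
  out <- list()
  for (kind in c("svm", "rf")) {
    factory <- if (kind == "svm") {
      svm_factory(svm_par$cost, svm_par$gamma)
    } else {
      rf_factory(config$n_trees, seed = config$seed)
    }
    model <- factory(X_train, y_train)
    s <- predict_scores(model, X_test)
    thr <- native_threshold(kind)
    out[[kind]] <- list(scores = s, pred = as.integer(s > thr),
                        threshold = thr)
  }
  out
}

#' Confusion-matrix metrics and AUC for one score set
#'
#' Accuracy, sensitivity, specificity, PPV and NPV (percent, recurrence =
#' positive) at the given threshold, plus Mann-Whitney AUC. The
#' ROC-optimal (Youden) threshold is also reported for reference.
#'
#' @param scores continuous scores; `labels` binary 0/1.
#' @param threshold decision threshold (prediction is `score > threshold`).
#' @return named numeric vector `acc, sen, spec, ppv, npv, auc, youden_j,
#'   youden_threshold`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0) {
  labels <- as.integer(labels)
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  auc <- if (length(unique(labels)) < 2) {
    warning("AUC undefined: one class absent in test labels")
    NA_real_
  } else {
    auc_score(scores, labels)
  }
  jt <- youden_optimal_threshold(scores, labels)
  c(acc = pct(tp + tn, length(labels)),
    sen = pct(tp, tp + fn), spec = pct(tn, tn + fp),
    ppv = pct(tp, tp + fp), npv = pct(tn, tn + fn),
    auc = auc, youden_j = youden_j(scores, labels),
    youden_threshold = jt)
}

youden_optimal_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) return(NA_real_)
  cuts <- sort(unique(scores), decreasing = TRUE)
  j <- vapply(cuts, function(ct) {
    pred <- scores >= ct
    sen <- sum(pred & labels == 1) / sum(labels == 1)
    spec <- sum(!pred & labels == 0) / sum(labels == 0)
    sen + spec - 1
  }, 0)
  cuts[which.max(j)]
}

#' Choose the better model per fold
#'
#' The model with the higher test-fold AUC wins; exact ties go to the SVM.
#'
#' @param svm_metrics,rf_metrics outputs of [compute_metrics()].
#' @return `"svm"` or `"rf"`.
#' @export
pick_better <- function(svm_metrics, rf_metrics) {
  a_svm <- svm_metrics["auc"]; a_rf <- rf_metrics["auc"]
  if (is.na(a_rf) || (!is.na(a_svm) && a_svm >= a_rf)) "svm" else "rf"
}

#' Stratified cross-validated evaluation of one region's features
#'
#' The full honest evaluation loop: within each outer training fold the
#' features are median-imputed and standardized, NCA weights and the
#' incremental AUC-maximizing subset are computed (training data only),
#' both classifiers are fitted on the selected features, the held-out fold
#' is scored, and the better model per fold (by test AUC) is retained.
#' Reported metrics are the mean over folds of the chosen model's metrics;
#' pooled test-fold scores support survival analysis on predictions.
#'
#' @param X feature matrix (rows = patients, may contain NA for empty
#'   bands).
#' @param y binary recurrence labels.
#' @param k outer fold count.
#' @param seed fold and model seed.
#' @param select run NCA + incremental selection (disable for low-dimensional
#'   baselines such as T/N stage).
#' @param inner_folds,K_cap,lambda selection settings (see
#'   [incremental_select()], [nca_weights()]); `lambda = "tune"` runs the
#'   inner-CV penalty grid search of [nca_tune_lambda()] per training fold.
#' @param config a [model_config()].
#' @param ids optional patient identifiers for canonical fold assignment.
#' @return object of class `cv_result`: `per_fold` data.frame (chosen model
#'   and metrics, plus the single-model `auc_svm`/`auc_rf` -- the chosen
#'   model's AUC is a per-fold maximum and therefore optimistic under the
#'   null, so calibration checks should use a single model's column),
#'   `aggregate` (mean metrics of chosen models), `pooled` data.frame of
#'   test-fold predictions, `selected` list of per-fold feature sets,
#'   `fold_id`, `seed`.
#' @export
run_region_cv <- function(X, y, k = 5L, seed = 1L, select = TRUE,
                          inner_folds = 5L, K_cap = 30L, lambda = NULL,
                          config = model_config(), ids = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  fold_id <- stratified_folds(y, k = k, seed = seed, ids = ids)
  per_fold <- list()
  pooled <- list()
  selected <- list()
  for (f in seq_len(k)) {
    tr <- fold_id != f
    med <- fit_imputer(X[tr, , drop = FALSE])
    Xtr <- apply_imputer(X[tr, , drop = FALSE], med)
    Xte <- apply_imputer(X[!tr, , drop = FALSE], med)
    keep <- apply(Xtr, 2, stats::sd) > 0
    if (!any(keep)) stop("all features constant in a training fold")
    Xtr <- Xtr[, keep, drop = FALSE]; Xte <- Xte[, keep, drop = FALSE]
    std <- fit_standardizer(Xtr)
    Xtr <- apply_standardizer(Xtr, std)
    Xte <- apply_standardizer(Xte, std)

    feats <- colnames(Xtr)
    if (select) {
      lam <- lambda
      if (identical(lambda, "tune")) {
        lam <- nca_tune_lambda(Xtr, y[tr],
                               grid = c(1, 4, 16, 64) / nrow(Xtr),
                               folds = 3L, seed = seed + f)
      }
      w <- nca_weights(Xtr, y[tr], lambda = lam)
      sub <- incremental_select(w, Xtr, y[tr], folds = inner_folds,
                                K_cap = K_cap, seed = seed + f)
      feats <- sub$features
    }
    selected[[f]] <- feats

    scored <- train_and_score(Xtr[, feats, drop = FALSE], y[tr],
                              Xte[, feats, drop = FALSE], config)
    m_svm <- compute_metrics(scored$svm$scores, y[!tr],
                             scored$svm$threshold)
    m_rf <- compute_metrics(scored$rf$scores, y[!tr], scored$rf$threshold)
    chosen <- pick_better(m_svm, m_rf)
    m <- if (chosen == "svm") m_svm else m_rf
    per_fold[[f]] <- data.frame(fold = f, model = chosen, t(m),
                                auc_svm = unname(m_svm["auc"]),
                                auc_rf = unname(m_rf["auc"]),
                                stringsAsFactors = FALSE)
    pooled[[f]] <- data.frame(
      index = which(!tr), fold = f, label = y[!tr],
      score = scored[[chosen]]$scores,
      pred = scored[[chosen]]$pred,
      model = chosen, stringsAsFactors = FALSE
    )
  }
  per_fold <- do.call(rbind, per_fold)
  pooled <- do.call(rbind, pooled)
  if (!is.null(ids)) pooled$patient_id <- ids[pooled$index]
  metric_cols <- c("acc", "sen", "spec", "ppv", "npv", "auc")
  aggregate <- colMeans(per_fold[, metric_cols, drop = FALSE], na.rm = TRUE)
  structure(list(per_fold = per_fold, aggregate = aggregate,
                 pooled = pooled, selected = selected, fold_id = fold_id,
                 seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf(
    "<cv_result> %d folds | ACC %.1f SEN %.1f SPEC %.1f AUC %.3f | models: %s\n",
    nrow(x$per_fold), a["acc"], a["sen"], a["spec"], a["auc"],
    paste(x$per_fold$model, collapse = ",")))
  invisible(x)
}

#' One-hot T/N-stage design matrix for the clinical baseline
#'
#' @param records clinical table with `t_stage` and `n_stage`.
#' @return numeric matrix of stage indicators.
#' @export
clinical_design_matrix <- function(records) {
  t_stage <- factor(records$t_stage, levels = c("T1", "T2", "T3"))
  n_stage <- factor(records$n_stage, levels = c("N0", "N1", "N2"))
  m <- stats::model.matrix(~ t_stage + n_stage,
                           data = data.frame(t_stage, n_stage))[, -1, drop = FALSE]
  rownames(m) <- records$patient_id
  m
}

#' Tumor-size subgroup labels
#'
#' AJCC size criteria: group 1 below 3 cm, group 2 at least 3 and below
#' 5 cm, group 3 at least 5 cm.
#'
#' @param diameter_cm tumor longest diameters in cm.
#' @return integer group labels 1/2/3.
#' @export
size_group <- function(diameter_cm) {
  ifelse(diameter_cm < 3, 1L, ifelse(diameter_cm < 5, 2L, 3L))
}

#' Re-run the evaluation within tumor-size subgroups
#'
#' Splits the cohort at 3 cm and 5 cm and repeats selection +
#' classification per region tag inside each stratum. Strata too small for
#' the requested fold count get a reduced count with a warning; strata
#' with a class below 2 members are skipped with `NULL`.
#'
#' @param records clinical table (needs `recurrence`,
#'   `tumor_longest_diameter`, `patient_id`).
#' @param feature_table wide table from [extract_feature_table()].
#' @param region_tags which regions to evaluate.
#' @param k requested fold count; other arguments as [run_region_cv()].
#' @param ... passed to [run_region_cv()].
#' @return nested list `result[[group]][[region_tag]]` of `cv_result`s.
#' @export
size_subgroup_analysis <- function(records, feature_table,
                                   region_tags = c("intra", "peri_30", "comb_30"),
                                   k = 5L, seed = 1L, ...) {
  grp <- size_group(records$tumor_longest_diameter)
  out <- list()
  for (g in 1:3) {
    sel <- grp == g
    res_g <- list()
    if (sum(sel) >= 10 && length(unique(records$recurrence[sel])) == 2) {
      min_class <- min(table(records$recurrence[sel]))
      k_g <- min(k, min_class)
      if (k_g < k) warning(sprintf(
        "size group %d: fold count reduced to %d", g, k_g))
      if (k_g >= 2) {
        for (tag in region_tags) {
          Xg <- region_design_matrix(feature_table, tag)[sel, , drop = FALSE]
          res_g[[tag]] <- run_region_cv(Xg, records$recurrence[sel],
                                        k = k_g, seed = seed,
                                        ids = records$patient_id[sel], ...)
        }
      }
    }
    out[[paste0("group", g)]] <- res_g
  }
  out
}
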