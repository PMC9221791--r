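test_that("stratified folds preserve class proportions within one patient", {
  # 103 non-recurrence vs 114 recurrence: folds of 20-21 and 22-23
  y <- rep(c(0, 1), c(103, 114))
  f <- stratified_folds(y, k = 5, seed = 3)
  tab <- table(f, y)
  expect_true(all(tab[, "0"] %in% 20:21))
  expect_true(all(tab[, "1"] %in% 22:23))
  expect_equal(sum(tab), 217)
})

test_that("fold assignment is canonical: input order does not matter", {
  set.seed(4)
  y <- rbinom(40, 1, 0.5)
  ids <- sprintf("P%02d", 1:40)
  f1 <- stratified_folds(y, k = 4, seed = 9, ids = ids)
  perm <- sample(40)
  f2 <- stratified_folds(y[perm], k = 4, seed = 9, ids = ids[perm])
  expect_equal(f1[perm], f2)
})

test_that("degenerate fold requests are rejected", {
  y <- rep(0:1, each = 10)
  expect_error(stratified_folds(y, k = 20, seed = 1), "smaller")
  expect_error(stratified_folds(y, k = 15, seed = 1))
  expect_error(stratified_folds(rep(1, 20), k = 5, seed = 1), "classes")
})

test_that("metrics at perfect and inverted scores hit their extremes", {
  y <- rep(c(0, 1), each = 10)
  s <- c(rep(-1, 10), rep(1, 10))
  m <- compute_metrics(s, y, threshold = 0)
  expect_equal(unname(m[c("acc", "sen", "spec", "ppv", "npv")]),
               rep(100, 5))
  expect_equal(unname(m["auc"]), 1)
  m_inv <- compute_metrics(-s, y, threshold = 0)
  expect_equal(unname(m_inv["auc"]), 0)
  expect_warning(compute_metrics(s, rep(1, 20)), "one class")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(12)
  for (i in 1:10) {
    s <- rnorm(30)
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(auc_score(exp(s), y), auc_score(s, y))
    expect_equal(auc_score(2 * s + 7, y), auc_score(s, y))
  }
})

test_that("rank-based AUC equals the pair-counting oracle and pROC", {
  set.seed(15)
  for (i in 1:10) {
    s <- sample(seq(0, 1, 0.05), 30, replace = TRUE)  # ties included
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    a <- auc_score(s, y)
    expect_equal(a, auc_pair_count(s, y))
    expect_equal(a, as.numeric(pROC::auc(pROC::roc(y, s, direction = "<",
                                                   levels = c(0, 1),
                                                   quiet = TRUE))))
  }
})

test_that("both models separate a linearly separable toy set", {
  set.seed(20)
  n <- 40
  y <- rep(0:1, each = n / 2)
  X <- cbind(a = y * 4 + rnorm(n, sd = 0.3), b = rnorm(n))
  scored <- train_and_score(X, y, X, model_config(seed = 1))
  expect_equal(as.integer(scored$svm$scores > 0), y)
  expect_gte(mean((scored$rf$scores > 0.5) == y), 0.95)
  expect_error(train_and_score(X[y == 1, ], y[y == 1], X), "single-class")
})

test_that("duplicating every training point preserves the SVM margin problem", {
  # duplicating the data doubles the hinge-loss term, so the duplicated
  # problem at cost C/2 is exactly the original problem at cost C
  set.seed(21)
  n <- 30
  y <- rep(0:1, each = n / 2)
  X <- cbind(a = y * 2 + rnorm(n), b = rnorm(n))
  Xte <- cbind(a = rnorm(10), b = rnorm(10))
  m1 <- svm_factory(cost = 2)(X, y)
  m2 <- svm_factory(cost = 1)(rbind(X, X), c(y, y))
  s1 <- predict_scores(m1, Xte)
  s2 <- predict_scores(m2, Xte)
  expect_lt(max(abs(s1 - s2)), 1e-3)
})

test_that("model choice per fold follows test AUC with ties going to the SVM", {
  m_svm <- c(auc = 0.7); m_rf <- c(auc = 0.6)
  expect_equal(pick_better(m_svm, m_rf), "svm")
  expect_equal(pick_better(c(auc = 0.6), c(auc = 0.7)), "rf")
  expect_equal(pick_better(c(auc = 0.65), c(auc = 0.65)), "svm")
})

test_that("cross-validated aggregate equals the mean of chosen-model fold metrics", {
  set.seed(22)
  n <- 50
  y <- rep(0:1, each = n / 2)
  X <- matrix(rnorm(n * 6), n, 6)
  colnames(X) <- paste0("f", 1:6)
  X[, 2] <- X[, 2] + 1.5 * y
  res <- run_region_cv(X, y, k = 5, seed = 7, inner_folds = 3, K_cap = 4)
  expect_equal(unname(res$aggregate["auc"]),
               mean(res$per_fold$auc))
  expect_setequal(res$pooled$index, 1:n)
  expect_true(all(res$per_fold$model %in% c("svm", "rf")))
  expect_length(res$selected, 5)
})

test_that("tumor-size group boundaries follow the AJCC cuts", {
  expect_equal(size_group(c(2.9, 3.0, 5.0)), c(1L, 2L, 3L))
  expect_equal(size_group(c(0.5, 4.99, 12)), c(1L, 2L, 3L))
})

test_that("size subgroups partition the cohort and reduce folds when small", {
  set.seed(30)
  records <- data.frame(
    patient_id = sprintf("P%03d", 1:60),
    recurrence = c(rep(0:1, 24), rep(0, 8), rep(1, 4)),
    tumor_longest_diameter = c(runif(30, 1, 2.9), runif(18, 3, 4.9),
                               runif(12, 5, 8)),
    stringsAsFactors = FALSE
  )
  grp <- size_group(records$tumor_longest_diameter)
  expect_equal(as.integer(table(grp)), c(30L, 18L, 12L))
  ft <- data.frame(patient_id = records$patient_id,
                   intra__f1 = rnorm(60) + records$recurrence,
                   intra__f2 = rnorm(60), check.names = FALSE)
  expect_warning(
    res <- size_subgroup_analysis(records, ft, region_tags = "intra",
                                  k = 5, seed = 1, select = FALSE),
    "reduced")
  expect_named(res, c("group1", "group2", "group3"))
  expect_s3_class(res$group1$intra, "cv_result")
})

test_that("clinical T/N design matrix one-hot encodes stages", {
  rec <- data.frame(patient_id = c("a", "b", "c"),
                    t_stage = c("T1", "T2", "T3"),
                    n_stage = c("N0", "N2", "N1"))
  m <- clinical_design_matrix(rec)
  expect_equal(dim(m), c(3L, 4L))
  expect_equal(unname(m["b", ]), c(1, 0, 0, 1))
})
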