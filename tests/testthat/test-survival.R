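test_that("Kaplan-Meier closed forms: no events, all events, subject doubling", {
  km0 <- kaplan_meier(c(10, 20, 30), c(0, 0, 0))
  expect_equal(km_at(km0, c(5, 25, 40)), c(1, 1, 1))

  km3 <- kaplan_meier(c(6, 12, 18), c(1, 1, 1))
  expect_equal(km_at(km3, c(6, 12, 18)), c(2 / 3, 1 / 3, 0))
  expect_equal(as.numeric(two_year_rfs(km3)), 0)
  expect_true(attr(two_year_rfs(km3), "truncated"))

  t <- c(3, 7, 12, 20, 30); e <- c(1, 0, 1, 0, 1)
  km1 <- kaplan_meier(t, e)
  km2 <- kaplan_meier(rep(t, 2), rep(e, 2))
  expect_equal(km_at(km2, km1$time), km1$surv)
})

test_that("KM without censoring equals the empirical survival function", {
  set.seed(41)
  for (i in 1:10) {
    t <- round(rexp(25, 0.05) + 0.5, 1)
    km <- kaplan_meier(t, rep(1, 25))
    grid <- seq(0.5, max(t) + 5, by = 1.7)
    expect_equal(km_at(km, grid),
                 sapply(grid, function(g) mean(t > g)))
  }
})

test_that("two-year RFS uses the left-continuous step convention", {
  # censoring just before 24 months does not move S(24) off the last event
  km <- kaplan_meier(c(6, 23.9, 30), c(1, 0, 0))
  expect_equal(as.numeric(two_year_rfs(km)), 2 / 3)
  expect_false(attr(two_year_rfs(km), "truncated"))
})

test_that("log-rank: identical groups, label symmetry, no-event degenerate case", {
  t <- c(5, 9, 14, 20); e <- c(1, 0, 1, 1)
  same <- log_rank(t, e, t, e)
  expect_equal(same$statistic, 0, tolerance = 1e-10)
  expect_equal(same$p_value, 1, tolerance = 1e-10)

  t2 <- c(3, 6, 10, 28); e2 <- c(1, 1, 1, 0)
  ab <- log_rank(t, e, t2, e2)
  ba <- log_rank(t2, e2, t, e)
  expect_equal(ab$statistic, ba$statistic)

  none <- log_rank(c(5, 10), c(0, 0), c(7, 12), c(0, 0))
  expect_equal(none$statistic, 0)
  expect_equal(none$p_value, 1)
})

test_that("log-rank statistic equals the hand-computed observed-expected form", {
  # six subjects, all events, distinct times: accumulate O-E and V by hand
  ta <- c(1, 4, 6); tb <- c(2, 3, 5)
  all_t <- sort(c(ta, tb))
  o_minus_e <- 0; v <- 0
  for (tt in all_t) {
    n_a <- sum(ta >= tt); n_b <- sum(tb >= tt); n <- n_a + n_b
    d <- 1                                   # one event at each time
    o <- as.numeric(tt %in% ta)
    e <- d * n_a / n
    o_minus_e <- o_minus_e + (o - e)
    if (n > 1) v <- v + d * (n_a / n) * (n_b / n) * (n - d) / (n - 1)
  }
  hand <- o_minus_e^2 / v
  lr <- log_rank(ta, rep(1, 3), tb, rep(1, 3))
  expect_equal(lr$statistic, hand, tolerance = 1e-10)
})

test_that("DeLong: AUC components match the pair-count oracle; identical scores degenerate", {
  set.seed(50)
  y <- rbinom(40, 1, 0.5); y[1:2] <- c(0, 1)
  s1 <- rnorm(40) + y
  s2 <- rnorm(40) + 0.5 * y
  dt <- delong_test(s1, s2, y)
  expect_equal(dt$auc_1, auc_pair_count(s1, y))
  expect_equal(dt$auc_2, auc_pair_count(s2, y))
  expect_false(dt$degenerate)
  expect_true(dt$p_value >= 0 && dt$p_value <= 1)

  same <- delong_test(s1, s1, y)
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)
})

test_that("DeLong agrees with the independent pROC implementation", {
  set.seed(51)
  for (i in 1:5) {
    y <- rep(0:1, each = 20)
    s1 <- rnorm(40) + 0.8 * y
    s2 <- 0.6 * s1 + rnorm(40, sd = 0.8)
    dt <- delong_test(s1, s2, y)
    ref <- pROC::roc.test(pROC::roc(y, s1, direction = "<", levels = c(0, 1),
                                    quiet = TRUE),
                          pROC::roc(y, s2, direction = "<", levels = c(0, 1),
                                    quiet = TRUE),
                          method = "delong", paired = TRUE)
    expect_equal(abs(dt$statistic), abs(as.numeric(ref$statistic)),
                 tolerance = 1e-8)
    expect_equal(dt$p_value, as.numeric(ref$p.value), tolerance = 1e-8)
  }
})

test_that("DeLong variance matches a subject-level bootstrap", {
  set.seed(52)
  n <- 100
  y <- rep(0:1, each = n / 2)
  s1 <- rnorm(n) + y
  s2 <- 0.5 * s1 + rnorm(n, sd = 0.9) + 0.3 * y
  dt <- delong_test(s1, s2, y)
  var_delong <- ((dt$auc_1 - dt$auc_2) / dt$statistic)^2
  boot <- replicate(2000, {
    idx <- sample(n, replace = TRUE)
    if (length(unique(y[idx])) < 2) return(NA_real_)
    auc_score(s1[idx], y[idx]) - auc_score(s2[idx], y[idx])
  })
  var_boot <- var(boot, na.rm = TRUE)
  expect_lt(abs(var_delong - var_boot) / var_boot, 0.15)
})

test_that("DeLong z is standard normal under the null of equal AUCs", {
  set.seed(53)
  z <- replicate(200, {
    n <- 60
    y <- rep(0:1, each = n / 2)
    base <- rnorm(n) + 0.8 * y
    s1 <- base + rnorm(n, sd = 0.6)
    s2 <- base + rnorm(n, sd = 0.6)
    delong_test(s1, s2, y)$statistic
  })
  expect_lt(abs(mean(z)), 0.2)
  expect_gt(var(z), 0.6)
  expect_lt(var(z), 1.5)
})

test_that("predicted-group survival splits the cohort and tests separation", {
  set.seed(54)
  n <- 60
  rec <- data.frame(
    time_months = c(runif(n / 2, 2, 24), runif(n / 2, 24, 60)),
    event = rep(c(1, 0), each = n / 2)
  )
  pooled <- data.frame(index = 1:n,
                       pred = rep(c(1, 0), each = n / 2))
  sv <- predicted_group_survival(rec, pooled)
  expect_lt(sv$rfs24_pred_rec, 0.05)
  expect_equal(sv$rfs24_pred_nonrec, 1)
  expect_lt(sv$test$p_value, 1e-6)
  df <- km_as_data_frame(sv$curve_pred_rec)
  expect_true(all(diff(df$surv) <= 0))
})
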