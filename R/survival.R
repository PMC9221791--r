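#' Kaplan-Meier curve of recurrence-free survival
#'
#' Product-limit estimate via [survival::survfit()], returned as a compact
#' step-function object. Deaths are processed before censorings at tied
#' times (the standard convention of the product-limit estimator).
#'
#' @param times positive follow-up times in months.
#' @param events binary event indicators (1 = recurrence observed).
#' @return object of class `km_curve`: `time`, `surv`, `n_risk`, `n_event`,
#'   `censor_times`, `max_follow_up`.
#' @export
kaplan_meier <- function(times, events) {
  stopifnot(length(times) > 0, all(times > 0),
            all(events %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event,
                 censor_times = times[events == 0],
                 max_follow_up = max(times)),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' Right-continuous step convention: the curve drops at event times and
#' `S(t)` carries the last event at or before `t`.
#'
#' @param curve a [kaplan_meier()] result.
#' @param t times in months.
#' @return survival probabilities.
#' @export
km_at <- function(curve, t) {
  sf <- stats::stepfun(curve$time, c(1, curve$surv), right = FALSE)
  sf(t)
}

#' Two-year recurrence-free survival probability
#'
#' `S(24 months)` from the product-limit curve. If no subject was followed
#' to 24 months, the estimate is extrapolation beyond the data and carries
#' a `truncated` attribute.
#'
#' @param curve a [kaplan_meier()] result.
#' @return probability, with attribute `truncated`.
#' @export
two_year_rfs <- function(curve) {
  s <- km_at(curve, 24)
  attr(s, "truncated") <- curve$max_follow_up < 24
  s
}

#' Two-group log-rank test
#'
#' Standard one-degree-of-freedom log-rank chi-square via
#' [survival::survdiff()]. With no events in either group, the statistic
#' is 0 and p = 1.
#'
#' @param times_a,events_a,times_b,events_b follow-up times and event
#'   indicators of the two groups.
#' @return list of class `surv_test`: `statistic`, `p_value`, `method`.
#' @export
log_rank <- function(times_a, events_a, times_b, events_b) {
  stopifnot(length(times_a) > 0, length(times_b) > 0)
  if (sum(events_a) + sum(events_b) == 0) {
    return(structure(list(statistic = 0, p_value = 1, method = "log-rank"),
                     class = "surv_test"))
  }
  time <- c(times_a, times_b)
  event <- c(events_a, events_b)
  group <- rep(c("a", "b"), c(length(times_a), length(times_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  structure(list(statistic = unname(sd$chisq),
                 p_value = stats::pchisq(sd$chisq, df = 1,
                                         lower.tail = FALSE),
                 method = "log-rank"),
            class = "surv_test")
}

#' @export
print.surv_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g\n",
              x$method, x$statistic, x$p_value))
  invisible(x)
}

# placement values of one score set: for each positive, the fraction of
# negatives it outranks (ties half credit), and symmetrically
placement_values <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  v10 <- vapply(pos, function(s) mean((s > neg) + 0.5 * (s == neg)), 0)
  v01 <- vapply(neg, function(s) mean((pos > s) + 0.5 * (pos == s)), 0)
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong test for two correlated (paired) AUCs
#'
#' Compares the AUCs of two score sets over the same subjects using the
#' placement-value covariance estimator; returns the z statistic and the
#' two-sided normal p-value. A zero-variance difference (e.g. identical
#' score vectors) yields p = 1 with a `degenerate` flag.
#'
#' @param scores_1,scores_2 paired continuous scores.
#' @param labels shared binary 0/1 labels (both classes present).
#' @return list of class `surv_test` with `statistic` (z), `p_value`,
#'   `auc_1`, `auc_2`, `degenerate`, `method`.
#' @export
delong_test <- function(scores_1, scores_2, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores_1) == length(labels),
            length(scores_2) == length(labels))
  m <- sum(labels == 1); n <- sum(labels == 0)
  if (m == 0 || n == 0) stop("both classes must be present")
  p1 <- placement_values(scores_1, labels)
  p2 <- placement_values(scores_2, labels)
  V10 <- cbind(p1$v10, p2$v10)
  V01 <- cbind(p1$v01, p2$v01)
  S10 <- stats::cov(V10)
  S01 <- stats::cov(V01)
  var_diff <- (S10[1, 1] + S10[2, 2] - 2 * S10[1, 2]) / m +
    (S01[1, 1] + S01[2, 2] - 2 * S01[1, 2]) / n
  degenerate <- !is.finite(var_diff) || var_diff <= .Machine$double.eps
  if (degenerate) {
    z <- 0; p <- 1
  } else {
    z <- (p1$auc - p2$auc) / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(statistic = z, p_value = p, auc_1 = p1$auc, auc_2 = p2$auc,
                 degenerate = degenerate, method = "delong"),
            class = "surv_test")
}

#' Kaplan-Meier curves and log-rank test for predicted groups
#'
#' Splits the cohort by pooled cross-validated predictions (recurrence vs
#' non-recurrence calls on held-out folds) and compares the two
#' recurrence-free survival curves.
#'
#' @param records clinical table with `time_months` and `event`.
#' @param pooled pooled predictions from a [run_region_cv()] result
#'   (`index`, `pred`).
#' @return list with `curve_pred_rec`, `curve_pred_nonrec`, `test`, and
#'   the two-year RFS of each predicted group.
#' @export
predicted_group_survival <- function(records, pooled) {
  idx_r <- pooled$index[pooled$pred == 1]
  idx_n <- pooled$index[pooled$pred == 0]
  if (length(idx_r) == 0 || length(idx_n) == 0) {
    return(list(curve_pred_rec = NULL, curve_pred_nonrec = NULL,
                test = NULL, rfs24_pred_rec = NA_real_,
                rfs24_pred_nonrec = NA_real_))
  }
  cr <- kaplan_meier(records$time_months[idx_r], records$event[idx_r])
  cn <- kaplan_meier(records$time_months[idx_n], records$event[idx_n])
  lt <- log_rank(records$time_months[idx_r], records$event[idx_r],
                 records$time_months[idx_n], records$event[idx_n])
  list(curve_pred_rec = cr, curve_pred_nonrec = cn, test = lt,
       rfs24_pred_rec = as.numeric(two_year_rfs(cr)),
       rfs24_pred_nonrec = as.numeric(two_year_rfs(cn)))
}

#' Export a Kaplan-Meier curve as a data frame
#'
#' @param curve a [kaplan_meier()] result.
#' @return data.frame with `time`, `surv`, `n_risk`, `n_event`.
#' @export
km_as_data_frame <- function(curve) {
  data.frame(time = curve$time, surv = curve$surv,
             n_risk = curve$n_risk, n_event = curve$n_event)
}
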