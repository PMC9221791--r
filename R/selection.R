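# Feature standardization and median imputation, fit on training data only
# so cross-validation folds stay leak-free.

#' Fit standardization parameters on training rows
#' @param X numeric matrix.
#' @return list with `center` and `scale` (zero-variance columns get scale 1).
#' @export
fit_standardizer <- function(X) {
  center <- colMeans(X, na.rm = TRUE)
  scale <- apply(X, 2, stats::sd, na.rm = TRUE)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

#' @rdname fit_standardizer
#' @param std a fitted standardizer.
#' @export
apply_standardizer <- function(X, std) {
  sweep(sweep(X, 2, std$center, "-"), 2, std$scale, "/")
}

#' Fit per-column median imputation on training rows
#'
#' Missing values arise when a peritumoral band is empty (tumor filling the
#' lung); they are imputed with training-fold medians before selection and
#' classification.
#' @param X numeric matrix.
#' @return named vector of medians (0 for all-NA columns).
#' @export
fit_imputer <- function(X) {
  med <- apply(X, 2, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  med
}

#' @rdname fit_imputer
#' @param med fitted medians.
#' @export
apply_imputer <- function(X, med) {
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- med[j]
  }
  X
}

#' Neighborhood component analysis feature weights
#'
#' Learns nonnegative per-feature weights by maximizing the expected
#' leave-one-out stochastic-nearest-neighbor classification accuracy under
#' the weighted L1 metric `d(i,j) = sum_r w_r^2 |x_ir - x_jr|`, minus an L2
#' penalty `lambda * sum w_r^2`. Neighbor probabilities use an exponential
#' kernel with row-wise stabilization. Optimization is deterministic
#' (full-batch L-BFGS-B from unit weights, bounded below at zero), so the
#' result depends only on the data and `lambda`.
#'
#' @param X numeric matrix (rows = samples), already standardized.
#' @param y binary labels (0/1), length `nrow(X)`.
#' @param lambda ridge penalty; `NULL` uses the conventional `1/n`.
#' @param maxit L-BFGS-B iteration cap.
#' @return object of class `nca_weights`: list with `weights` (named,
#'   >= 0), `lambda`, `converged`, `objective`.
#' @export
nca_weights <- function(X, y, lambda = NULL, maxit = 100L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(n >= 10, length(y) == n)
  if (!all(is.finite(X))) stop("non-finite values in feature matrix")
  y <- as.integer(y)
  if (is.null(lambda)) lambda <- 1 / n
  same <- outer(y, y, "==")
  diag(same) <- FALSE

  # |x_ir - x_jr| flattened to an n^2 x p matrix, computed once
  A <- matrix(0, n * n, p)
  for (r in seq_len(p)) {
    A[, r] <- abs(outer(X[, r], X[, r], "-"))
  }

  eval_fg <- function(w) {
    d <- matrix(A %*% (w^2), n, n)
    diag(d) <- Inf
    dmin <- apply(d, 1, min)
    dmin[!is.finite(dmin)] <- 0
    K <- exp(-(d - dmin))
    diag(K) <- 0
    rs <- rowSums(K)
    rs[rs == 0] <- 1
    Pij <- K / rs
    pi_i <- rowSums(Pij * same)
    f <- mean(pi_i) - lambda * sum(w^2)
    coef <- Pij * (pi_i - same) / n       # n x n
    g <- 2 * w * as.vector(crossprod(A, as.vector(coef))) - 2 * lambda * w
    list(f = f, g = g)
  }

  opt <- stats::optim(
    par = rep(1, p),
    fn = function(w) -eval_fg(w)$f,
    gr = function(w) -eval_fg(w)$g,
    method = "L-BFGS-B", lower = 0,
    control = list(maxit = maxit)
  )
  w <- pmax(opt$par, 0)
  names(w) <- colnames(X)
  structure(list(weights = w, lambda = lambda,
                 converged = opt$convergence == 0,
                 objective = -opt$value),
            class = "nca_weights")
}

#' @export
print.nca_weights <- function(x, ...) {
  top <- sort(x$weights, decreasing = TRUE)
  top <- top[seq_len(min(5, length(top)))]
  cat(sprintf("<nca_weights> %d features, lambda = %.4g, converged = %s\n",
              length(x$weights), x$lambda, x$converged))
  cat("top weights:", paste(sprintf("%s=%.3f", names(top), top),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Tune the NCA ridge penalty by inner cross-validation
#'
#' Fits weights for each candidate `lambda` on inner training folds and
#' scores the weighted-metric 1-nearest-neighbor error on the held-out
#' fold; returns the error-minimizing penalty.
#'
#' @param X standardized matrix; `y` binary labels.
#' @param grid candidate penalties (default a small log grid around 1/n).
#' @param folds inner fold count.
#' @param seed fold-assignment seed.
#' @return the selected lambda.
#' @export
nca_tune_lambda <- function(X, y, grid = NULL, folds = 5L, seed = 1L) {
  n <- nrow(X)
  if (is.null(grid)) grid <- c(0.25, 0.5, 1, 2, 4) / n
  fold_id <- stratified_folds(y, k = folds, seed = seed)
  errs <- vapply(grid, function(lam) {
    e <- 0
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (length(unique(y[tr])) < 2) next
      w <- nca_weights(X[tr, , drop = FALSE], y[tr], lambda = lam,
                       maxit = 40L)$weights
      d <- weighted_l1_cross(X[!tr, , drop = FALSE], X[tr, , drop = FALSE],
                             w^2)
      pred <- y[tr][apply(d, 1, which.min)]
      e <- e + sum(pred != y[!tr])
    }
    e
  }, 0)
  grid[which.min(errs)]
}

# cross weighted-L1 distances between row sets
weighted_l1_cross <- function(A, B, w2) {
  out <- matrix(0, nrow(A), nrow(B))
  for (r in seq_len(ncol(A))) {
    out <- out + w2[r] * abs(outer(A[, r], B[, r], "-"))
  }
  out
}

#' Incremental AUC-maximizing feature subset selection
#'
#' Features are ranked by descending NCA weight and added one at a time;
#' each prefix subset of size k = 1..K is scored by the mean inner
#' cross-validated AUC of the classifier. The subset maximizing AUC wins;
#' exact AUC ties are broken by the larger Youden's J (sensitivity +
#' specificity - 1 at the ROC-optimal threshold of the pooled inner-CV
#' scores), and any remaining tie by the smaller subset.
#'
#' @param weights an [nca_weights()] object fitted on the same training
#'   data.
#' @param X standardized training matrix; `y` binary labels.
#' @param classifier_factory function `(X, y) -> model` whose model is
#'   scored with [predict_scores()]; default RBF-SVM.
#' @param folds inner fold count (reduced automatically for tiny classes).
#' @param K_cap maximum subset size examined.
#' @param seed fold-assignment seed.
#' @return object of class `selected_subset`: list with `features` (in
#'   weight order), `achieved_auc`, `achieved_youden_j`, `auc_path`.
#' @export
incremental_select <- function(weights, X, y, classifier_factory = NULL,
                               folds = 5L, K_cap = 30L, seed = 1L) {
  stopifnot(inherits(weights, "nca_weights"))
  if (is.null(classifier_factory)) classifier_factory <- svm_factory()
  w <- weights$weights
  if (all(apply(X, 2, stats::sd) == 0)) stop("all features are constant")
  ord <- order(-w, seq_along(w))   # descending weight, stable in column order
  ranked <- colnames(X)[ord]
  K <- min(K_cap, ncol(X))
  y <- as.integer(y)
  k_eff <- min(folds, min(table(y)))
  if (k_eff < 2) stop("too few samples per class for inner CV")
  fold_id <- stratified_folds(y, k = k_eff, seed = seed)

  auc_path <- numeric(K)
  j_path <- numeric(K)
  for (k in seq_len(K)) {
    feats <- ranked[seq_len(k)]
    pooled_s <- numeric(0); pooled_y <- integer(0); fold_auc <- numeric(0)
    for (f in seq_len(k_eff)) {
      tr <- fold_id != f
      Xtr <- X[tr, feats, drop = FALSE]; Xte <- X[!tr, feats, drop = FALSE]
      if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) next
      model <- classifier_factory(Xtr, y[tr])
      s <- predict_scores(model, Xte)
      fold_auc <- c(fold_auc, auc_score(s, y[!tr]))
      pooled_s <- c(pooled_s, s); pooled_y <- c(pooled_y, y[!tr])
    }
    auc_path[k] <- if (length(fold_auc)) mean(fold_auc) else NA_real_
    j_path[k] <- if (length(pooled_s)) youden_j(pooled_s, pooled_y) else NA_real_
  }

  best_auc <- max(auc_path, na.rm = TRUE)
  cand <- which(!is.na(auc_path) & abs(auc_path - best_auc) < 1e-12)
  if (length(cand) > 1) {
    best_j <- max(j_path[cand])
    cand <- cand[abs(j_path[cand] - best_j) < 1e-12]
  }
  k_star <- min(cand)
  structure(list(features = ranked[seq_len(k_star)],
                 achieved_auc = auc_path[k_star],
                 achieved_youden_j = j_path[k_star],
                 auc_path = auc_path),
            class = "selected_subset")
}

#' @export
print.selected_subset <- function(x, ...) {
  cat(sprintf("<selected_subset> %d features, inner-CV AUC %.3f (J %.3f)\n",
              length(x$features), x$achieved_auc, x$achieved_youden_j))
  invisible(x)
}

#' Youden's J at the ROC-optimal threshold
#'
#' Maximum of sensitivity + specificity - 1 over all score thresholds.
#' @param scores continuous scores (higher = more positive).
#' @param labels binary 0/1 labels.
#' @return J in \[-1, 1\].
#' @export
youden_j <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[ord] == 1)
  fp <- cumsum(labels[ord] == 0)
  # evaluate only at distinct-score cut points (and the empty cut)
  s <- scores[ord]
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  sens <- c(0, tp[last_of_tie]) / n1
  spec <- c(1, 1 - fp[last_of_tie] / n0)
  max(sens + spec - 1)
}
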