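# SVM-RBF training, grid search, cross-validation and the evaluation
# metrics (overall accuracy, per-class sensitivity/specificity/MCC).
#
# The SVM itself is LIBSVM via e1071 (C-classification, one-vs-one
# multi-class decomposition).  Features are rescaled fold-locally to
# [0, 1] per feature (the LIBSVM svm-scale convention): scaling
# parameters are fit on the training rows only and applied to the test
# rows, so no information leaks across folds.  Range scaling, not
# z-scoring, keeps squared distances small enough that the adopted
# gamma = 0.055 stays in a useful kernel regime for ~600 features.

.split_feature_table <- function(features) {
  stopifnot(is.data.frame(features))
  meta <- intersect(c("protein_id", "class"), names(features))
  x <- as.matrix(features[, setdiff(names(features), meta), drop = FALSE])
  if (!is.numeric(x) || ncol(x) == 0) {
    rlang::abort("feature table must contain numeric feature columns")
  }
  y <- if ("class" %in% meta) features$class else NULL
  list(x = x, y = y)
}

.fit_scaler <- function(x) {
  lo <- apply(x, 2, min)
  range <- apply(x, 2, max) - lo
  range[!is.finite(range) | range == 0] <- 1  # constant columns -> zeros
  list(center = lo, scale = range)
}

.apply_scaler <- function(x, scaler) {
  sweep(sweep(x, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

#' Train an RBF-kernel support vector machine
#'
#' Fits a multi-class C-SVM with Gaussian kernel
#' `K(x, x') = exp(-gamma * ||x - x'||^2)` using LIBSVM's one-vs-one
#' decomposition (via e1071).  Features are rescaled to \[0, 1\] per
#' feature using ranges of the training rows (the LIBSVM `svm-scale`
#' convention); the fitted scaler is stored so that
#' [predict.segstruct_svm()] applies the same transform to new data.
#' Defaults are the adopted operating point C = 500, gamma = 0.055.
#'
#' @param features Tibble with a `class` column and numeric feature
#'   columns (a `protein_id` column is ignored), e.g. from
#'   [extract_dataset()].
#' @param cost Soft-margin cost C (> 0).
#' @param gamma RBF kernel width (> 0).
#' @return An object of class `segstruct_svm`.
#' @export
train_svm <- function(features, cost = 500, gamma = 0.055) {
  sp <- .split_feature_table(features)
  if (is.null(sp$y)) rlang::abort("feature table has no `class` column")
  y <- factor(sp$y, levels = intersect(structural_classes(), unique(sp$y)))
  if (nlevels(y) < 2) {
    rlang::abort("training set must contain at least two classes")
  }
  scaler <- .fit_scaler(sp$x)
  xs <- .apply_scaler(sp$x, scaler)
  fit <- e1071::svm(xs, y, type = "C-classification", kernel = "radial",
                    cost = cost, gamma = gamma, scale = FALSE)
  structure(list(fit = fit, scaler = scaler, levels = levels(y),
                 cost = cost, gamma = gamma,
                 feature_names = colnames(sp$x)),
            class = "segstruct_svm")
}

#' Predict structural classes with a trained SVM
#'
#' @param object A `segstruct_svm` from [train_svm()].
#' @param newdata Tibble or matrix with the same feature columns the model
#'   was trained on.
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.segstruct_svm <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    newdata <- .split_feature_table(newdata)$x
  }
  newdata <- newdata[, object$feature_names, drop = FALSE]
  xs <- .apply_scaler(newdata, object$scaler)
  as.character(stats::predict(object$fit, xs))
}

# stratified fold assignment; classes smaller than k fall back to
# round-robin with a warning
.make_folds <- function(y, k, seed) {
  n <- length(y)
  fold <- integer(n)
  withr::with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      if (length(idx) < k) {
        rlang::warn(sprintf(
          "class '%s' has %d member(s), fewer than k = %d folds: assigning round-robin without stratification",
          cl, length(idx), k))
      }
      fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Cross-validate an SVM over a feature table
#'
#' Evaluates the classifier by stratified k-fold cross-validation or the
#' jackknife (leave-one-out).  Every protein is predicted exactly once
#' from a model trained on the remaining folds, with feature scaling
#' refit inside each training fold; the pooled
#' out-of-fold predictions form the confusion matrix and metrics.  The
#' jackknife has no randomness; k-fold fold assignment is stratified by
#' class and driven entirely by `seed`, so equal seeds give identical
#' reports.
#'
#' @param features Tibble with `protein_id` (optional), `class`, and
#'   numeric feature columns.
#' @param scheme `"kfold"` or `"jackknife"`.
#' @param k Number of folds for `"kfold"` (2 ... 10 in the studied range).
#' @param seed Integer seed for fold construction.
#' @param cost,gamma SVM parameters, see [train_svm()].
#' @return An object of class `cv_report`; see [compute_metrics()],
#'   [tidy.cv_report()], [glance.cv_report()] and [autoplot.cv_report()].
#' @export
cross_validate <- function(features, scheme = c("jackknife", "kfold"),
                           k = 10, seed = 1, cost = 500, gamma = 0.055) {
  scheme <- match.arg(scheme)
  sp <- .split_feature_table(features)
  if (is.null(sp$y)) rlang::abort("feature table has no `class` column")
  y <- as.character(sp$y)
  n <- length(y)
  if (scheme == "jackknife") {
    fold <- seq_len(n)
    k_used <- n
  } else {
    if (n < k) rlang::abort(sprintf("need at least k = %d samples, have %d", k, n))
    fold <- .make_folds(y, k, seed)
    k_used <- k
  }
  pred <- character(n)
  df <- features
  for (f in sort(unique(fold))) {
    test <- fold == f
    model <- train_svm(df[!test, , drop = FALSE], cost = cost, gamma = gamma)
    pred[test] <- predict(model, df[test, , drop = FALSE])
  }
  lev <- intersect(structural_classes(), unique(c(y, pred)))
  confusion <- table(factor(y, lev), factor(pred, lev))
  confusion <- unclass(confusion)
  names(dimnames(confusion)) <- c("true", "predicted")
  rep <- compute_metrics(confusion)
  rep$scheme <- scheme
  rep$k <- k_used
  rep$seed <- if (scheme == "jackknife") NA_integer_ else seed
  rep$cost <- cost
  rep$gamma <- gamma
  rep$predictions <- tibble::tibble(
    protein_id = if ("protein_id" %in% names(features))
      features$protein_id else as.character(seq_len(n)),
    class = y, predicted = pred, fold = fold)
  rep
}

#' Classification metrics from a confusion matrix
#'
#' Overall accuracy is `Q = 100 * trace / N` (percent).  Per class, the
#' confusion matrix is collapsed one-vs-rest: `TP` is the diagonal entry,
#' `FN` the rest of the row, `FP` the rest of the column and
#' `TN = N - TP - FN - FP`; then sensitivity `TP / (TP + FN)`,
#' specificity `TN / (TN + FP)` (proportions in \[0, 1\]), and the
#' Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, defined as 0
#' when any factor of the denominator is zero (the random-correlation
#' value).
#'
#' @param confusion Square non-negative integer matrix, rows = true
#'   classes, columns = predicted, matching dimnames.
#' @return An object of class `cv_report` with elements `confusion`,
#'   `overall_accuracy` (percent), `per_class` (tibble with class,
#'   sensitivity, specificity, mcc) and `n`.
#' @export
compute_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (any(confusion < 0) || any(confusion != round(confusion))) {
    rlang::abort("confusion matrix must contain non-negative integers")
  }
  N <- sum(confusion)
  if (N == 0) rlang::abort("confusion matrix is all zero")
  classes <- rownames(confusion) %||% as.character(seq_len(nrow(confusion)))
  per <- purrr::map_dfr(seq_len(nrow(confusion)), function(c) {
    TP <- confusion[c, c]
    FN <- sum(confusion[c, ]) - TP
    FP <- sum(confusion[, c]) - TP
    TN <- N - TP - FN - FP
    denom2 <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
    tibble::tibble(
      class = classes[[c]],
      sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
      specificity = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
      mcc = if (denom2 == 0) 0 else (TP * TN - FP * FN) / sqrt(denom2))
  })
  structure(list(confusion = confusion,
                 overall_accuracy = 100 * sum(diag(confusion)) / N,
                 per_class = per, n = N),
            class = "cv_report")
}

#' Grid search for SVM cost and gamma
#'
#' Evaluates every (C, gamma) pair of a powers-of-two grid by mean
#' stratified k-fold cross-validation accuracy and returns the best pair;
#' ties are broken by smaller C, then smaller gamma.  The default grid is
#' the conventional coarse LIBSVM range, C in 2^-5 ... 2^15 and gamma in
#' 2^-15 ... 2^3, with exponent step 2.
#'
#' @param features Tibble with `class` and numeric feature columns.
#' @param cost_grid,gamma_grid Numeric vectors of candidate values.
#' @param k Folds for the inner cross-validation (default 10).
#' @param seed Integer seed for fold construction (shared across pairs).
#' @return List with `cost`, `gamma`, `cv_accuracy` (percent) and `grid`
#'   (tibble of all pairs and their accuracies).
#' @export
grid_search <- function(features,
                        cost_grid = 2^seq(-5, 15, by = 2),
                        gamma_grid = 2^seq(-15, 3, by = 2),
                        k = 10, seed = 1) {
  if (length(cost_grid) == 0 || length(gamma_grid) == 0) {
    rlang::abort("grid must be non-empty")
  }
  grid <- tidyr::expand_grid(cost = sort(cost_grid), gamma = sort(gamma_grid))
  acc <- purrr::map2_dbl(grid$cost, grid$gamma, function(C, g) {
    cross_validate(features, scheme = "kfold", k = k, seed = seed,
                   cost = C, gamma = g)$overall_accuracy
  })
  grid$cv_accuracy <- acc
  best <- grid |>
    dplyr::arrange(dplyr::desc(.data$cv_accuracy), .data$cost, .data$gamma) |>
    dplyr::slice(1)
  list(cost = best$cost, gamma = best$gamma,
       cv_accuracy = best$cv_accuracy, grid = grid)
}

#' Add-one-group ablation experiment
#'
#' Reproduces the add-one-group protocol: starting from the first feature
#' group, groups are added cumulatively and each prefix is scored by mean
#' stratified k-fold cross-validation accuracy on the given feature table.
#'
#' @param features Feature table containing at least the columns of all
#'   requested groups (e.g. a full combined table).
#' @param groups Character vector of group names in the order they are
#'   added, e.g. `c("PSSM_AAC", "PSSM_SAC", "PSSM_SD", "AAO")`.
#' @param k,seed,cost,gamma Passed to [cross_validate()].
#' @return Tibble with one row per cumulative prefix: `groups` (label),
#'   `n_features`, `accuracy` (percent).
#' @export
run_ablation <- function(features,
                         groups = c("PSSM_AAC", "PSSM_SAC", "PSSM_SD", "AAO"),
                         k = 10, seed = 1, cost = 500, gamma = 0.055) {
  grp_of <- feature_groups_of(names(features))
  purrr::map_dfr(seq_along(groups), function(i) {
    keep <- names(features)[!is.na(grp_of) & grp_of %in% groups[1:i]]
    if (length(keep) == 0) {
      rlang::abort(sprintf("no columns found for group(s) %s",
                           paste(groups[1:i], collapse = "+")))
    }
    sub <- features[, c(intersect(c("protein_id", "class"), names(features)),
                        keep), drop = FALSE]
    rep <- cross_validate(sub, scheme = "kfold", k = k, seed = seed,
                          cost = cost, gamma = gamma)
    tibble::tibble(groups = paste(groups[1:i], collapse = "+"),
                   n_features = length(keep),
                   accuracy = rep$overall_accuracy)
  })
}
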