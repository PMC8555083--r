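# Two-stage classification: SAE dimensionality reduction followed by a
# linear SVM, evaluated with stratified k-fold outer cross-validation,
# nested hyperparameter search, and a label-permutation significance test.

#' Balanced accuracy from sensitivity and specificity
#'
#' The aggregator used for every reported performance value:
#' `(sensitivity + specificity) / 2`.
#'
#' @param sensitivity,specificity Rates in \[0, 1\] (scalars or vectors).
#' @return Balanced accuracy on the same scale.
#' @export
balanced_accuracy <- function(sensitivity, specificity) {
  (sensitivity + specificity) / 2
}

# sensitivity/specificity/balanced accuracy of predictions vs truth
classification_metrics <- function(pred, truth, positive) {
  pred <- as.character(pred); truth <- as.character(truth)
  sens <- mean(pred[truth == positive] == positive)
  spec <- mean(pred[truth != positive] != positive)
  list(sensitivity = sens, specificity = spec,
       balanced_accuracy = balanced_accuracy(sens, spec))
}

#' Seeded stratified fold assignment
#'
#' Shuffles subjects once (seeded) and deals each class cyclically into `k`
#' folds, so per-fold class counts differ by at most one subject from exact
#' proportionality.
#'
#' @param y Factor of class labels.
#' @param k Number of folds.
#' @param seed Seed for the shuffle.
#' @return Integer vector of fold ids (1..k), one per subject.
#' @export
stratified_folds <- function(y, k, seed = 1L) {
  y <- factor(y)
  k <- as.integer(k)
  if (min(table(y)) < k) {
    stop(sprintf("smallest class has %d members; use k <= that", min(table(y))))
  }
  folds <- integer(length(y))
  with_seed(seed, {
    for (lv in levels(y)) {
      idx <- sample(which(y == lv))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# Training-fold standardizer: non-finite entries are imputed with the
# training-fold median, then columns are z-scored with training statistics.
fit_standardizer <- function(x) {
  x[!is.finite(x)] <- NA
  med <- apply(x, 2, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- med[j]
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(median = med, mean = mu, sd = sd)
}

apply_standardizer <- function(st, x) {
  for (j in seq_len(ncol(x))) x[!is.finite(x[, j]), j] <- st$median[j]
  sweep(sweep(x, 2, st$mean), 2, st$sd, "/")
}

#' Linear SVM with nested hyperparameter search
#'
#' Selects the soft-margin cost `C` from `c_grid` by stratified `k_inner`-fold
#' cross-validation on the training codes (maximizing mean inner balanced
#' accuracy; ties go to the smallest `C`, i.e. the strongest regularization),
#' then refits a linear SVM with the chosen `C` on all of `z`.
#'
#' @param z Code matrix (training subjects x code dimensions).
#' @param y Binary factor of labels.
#' @param c_grid Candidate costs (default `10^(-3:4)`).
#' @param k_inner Inner folds (default 5; reduced with a warning when a class
#'   is smaller than `k_inner`).
#' @param seed Seed for the inner fold shuffle.
#' @return List with `model` (an [e1071::svm()] fit), `chosen_c`, and
#'   `inner_accuracy` (mean inner balanced accuracy per candidate).
#' @export
train_svm_nested <- function(z, y, c_grid = 10^(-3:4), k_inner = 5L, seed = 1L) {
  z <- as.matrix(z)
  y <- droplevels(factor(y))
  if (nlevels(y) != 2L) stop("y must have exactly 2 classes")
  c_grid <- sort(as.numeric(c_grid))
  k <- as.integer(k_inner)
  smallest <- min(table(y))
  if (smallest < k) {
    warning(sprintf("class with %d members < k_inner = %d; using k = %d",
                    smallest, k, smallest))
    k <- smallest
  }
  if (k < 2L) stop("need at least 2 members per class for inner CV")
  folds <- stratified_folds(y, k, seed)
  positive <- levels(y)[1]
  inner <- vapply(c_grid, function(cc) {
    mean(vapply(seq_len(k), function(f) {
      tr <- folds != f
      fit <- e1071::svm(z[tr, , drop = FALSE], y[tr], kernel = "linear",
                        cost = cc, scale = FALSE)
      pred <- stats::predict(fit, z[!tr, , drop = FALSE])
      classification_metrics(pred, y[!tr], positive)$balanced_accuracy
    }, numeric(1)))
  }, numeric(1))
  chosen <- c_grid[which(inner >= max(inner) - 1e-12)[1]]
  model <- e1071::svm(z, y, kernel = "linear", cost = chosen, scale = FALSE)
  list(model = model, chosen_c = chosen,
       inner_accuracy = stats::setNames(inner, format(c_grid)))
}

#' Cross-validated two-stage SAE + SVM pipeline
#'
#' Stratified `k_outer`-fold evaluation of the full pipeline. Within each
#' fold, every training statistic -- feature standardization, SAE pretraining
#' and fine-tuning, and the nested SVM search -- is computed from the
#' training partition only; the held-out partition is transformed with those
#' frozen statistics and predicted once.
#'
#' @param x Feature matrix (subjects x features) or a [feature_table()].
#' @param y Binary factor of group labels (ignored and taken from the table
#'   when `x` is a [feature_table()]); the first factor level is the positive
#'   class for sensitivity.
#' @param k_outer Outer folds (default 10).
#' @param seed Master seed; fold assignment and all per-fold training seeds
#'   derive from it.
#' @param layer_sizes,hyper SAE architecture and training settings.
#' @param c_grid,k_inner Nested SVM search settings.
#' @return An object of class `cv_result`: `per_fold` data frame
#'   (sensitivity, specificity, balanced accuracy, chosen C), `mean` and `sd`
#'   of each metric over folds, `folds` assignment, `positive_class`, `seed`.
#' @export
cross_validate_pipeline <- function(x, y = NULL, k_outer = 10L, seed = 1L,
                                    layer_sizes = c(128L, 64L, 32L, 10L),
                                    hyper = sae_hyper(), c_grid = 10^(-3:4),
                                    k_inner = 5L) {
  if (inherits(x, "feature_table")) {
    y <- ft_labels(x)
    x <- ft_matrix(x)
  }
  x <- as.matrix(x)
  y <- droplevels(factor(y))
  if (nlevels(y) != 2L) stop("y must have exactly 2 classes")
  positive <- levels(y)[1]
  folds <- stratified_folds(y, k_outer, seed)
  rows <- lapply(seq_len(k_outer), function(f) {
    tr <- folds != f
    st <- fit_standardizer(x[tr, , drop = FALSE])
    xt <- apply_standardizer(st, x[tr, , drop = FALSE])
    xe <- apply_standardizer(st, x[!tr, , drop = FALSE])
    pre <- pretrain_autoencoders(xt, layer_sizes, hyper,
                                 seed = derive_seed(seed, 10 + f))
    model <- fine_tune_supervised(pre, xt, y[tr], hyper,
                                  seed = derive_seed(seed, 200 + f))
    zt <- encode(model, xt)
    ze <- encode(model, xe)
    svm_fit <- train_svm_nested(zt, y[tr], c_grid, k_inner,
                                seed = derive_seed(seed, 300 + f))
    pred <- stats::predict(svm_fit$model, ze)
    met <- classification_metrics(pred, y[!tr], positive)
    data.frame(fold = f, sensitivity = met$sensitivity,
               specificity = met$specificity,
               balanced_accuracy = met$balanced_accuracy,
               chosen_c = svm_fit$chosen_c)
  })
  per_fold <- do.call(rbind, rows)
  metr <- c("sensitivity", "specificity", "balanced_accuracy")
  structure(
    list(per_fold = per_fold,
         mean = vapply(per_fold[metr], mean, numeric(1)),
         sd = vapply(per_fold[metr], stats::sd, numeric(1)),
         folds = folds, positive_class = positive, seed = seed,
         layer_sizes = layer_sizes, hyper = hyper),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %d folds | balanced accuracy %.3f +/- %.3f | sensitivity %.3f | specificity %.3f\n",
    nrow(x$per_fold), x$mean["balanced_accuracy"], x$sd["balanced_accuracy"],
    x$mean["sensitivity"], x$mean["specificity"]
  ))
  invisible(x)
}

#' Label-permutation significance test
#'
#' Re-runs the full cross-validated pipeline `n_perm` times with randomly
#' permuted group labels and compares the permuted mean balanced accuracies
#' with the observed one. The p value is
#' `count(permuted >= observed) / n_perm` (ties count against significance);
#' when the count is 0 the reported label is `"< 1/n_perm"`.
#'
#' @param x Feature matrix or [feature_table()].
#' @param y Labels (see [cross_validate_pipeline()]).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Master seed (permutation draws derive from it; the pipeline
#'   seed is held fixed across permutations).
#' @param ... Passed to [cross_validate_pipeline()].
#' @return An object of class `permutation_result`: `observed` (mean balanced
#'   accuracy), `null` (length `n_perm`), `p_value`, `p_label`, `n_perm`,
#'   `seed`, and the observed `cv` result.
#' @export
permutation_test <- function(x, y = NULL, n_perm = 1000L, seed = 1L, ...) {
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (inherits(x, "feature_table")) {
    y <- ft_labels(x)
    x <- ft_matrix(x)
  }
  cv <- cross_validate_pipeline(x, y, seed = seed, ...)
  observed <- unname(cv$mean["balanced_accuracy"])
  null <- vapply(seq_len(n_perm), function(b) {
    yb <- with_seed(derive_seed(seed, 7000 + b), sample(y))
    cvb <- cross_validate_pipeline(x, yb, seed = seed, ...)
    unname(cvb$mean["balanced_accuracy"])
  }, numeric(1))
  count <- sum(null >= observed)
  structure(
    list(observed = observed, null = null,
         p_value = count / n_perm,
         p_label = if (count == 0) sprintf("< %g", 1 / n_perm)
                   else format(count / n_perm),
         n_perm = n_perm, seed = seed, cv = cv),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> observed %.3f | null mean %.3f | p %s (n_perm = %d)\n",
              x$observed, mean(x$null), x$p_label, x$n_perm))
  invisible(x)
}
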