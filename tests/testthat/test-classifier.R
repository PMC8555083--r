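# low-rank separable toy data used across classifier tests
make_separable <- function(n_per_class = 30, dim = 40, gap = 3, seed = 1) {
  set.seed(seed)
  z <- matrix(rnorm(2 * n_per_class * 5), 2 * n_per_class, 5)
  z[seq_len(n_per_class), 1] <- z[seq_len(n_per_class), 1] + gap
  proj <- matrix(rnorm(5 * dim), 5, dim)
  list(x = z %*% proj + 0.01 * matrix(rnorm(2 * n_per_class * dim),
                                      2 * n_per_class, dim),
       y = factor(rep(c("A", "B"), each = n_per_class)))
}

test_that("balanced accuracy is the mean of sensitivity and specificity", {
  expect_equal(balanced_accuracy(0.597, 0.827), 0.712)
  expect_equal(balanced_accuracy(1, 0), 0.5)
  expect_equal(balanced_accuracy(c(0.5, 1), c(0.5, 1)), c(0.5, 1))
})

test_that("stratified folds partition subjects with balanced class counts", {
  y <- factor(rep(c("A", "B"), c(33, 53)))
  folds <- stratified_folds(y, 10, seed = 1)
  expect_length(folds, 86)
  expect_equal(sort(unique(folds)), 1:10)
  tab <- table(folds, y)
  expect_true(all(tab[, "A"] %in% 3:4))
  expect_true(all(tab[, "B"] %in% 5:6))
  # deterministic under the seed
  expect_identical(folds, stratified_folds(y, 10, seed = 1))
  expect_false(identical(folds, stratified_folds(y, 10, seed = 2)))
  expect_error(stratified_folds(factor(rep(c("A", "B"), c(3, 50))), 10),
               "class")
})

test_that("pretraining is seeded and untrained weights equal initialization", {
  d <- make_separable()
  h0 <- sae_hyper(pretrain_epochs = 0)
  p1 <- pretrain_autoencoders(d$x, c(16L, 8L), h0, seed = 5)
  p2 <- pretrain_autoencoders(d$x, c(16L, 8L), h0, seed = 5)
  expect_identical(p1$W, p2$W)
  expect_equal(dim(p1$W[[1]]), c(16, 40))
  expect_equal(dim(p1$W[[2]]), c(8, 16))
  # zero epochs leaves Glorot-initialized weights untouched by training
  p3 <- pretrain_autoencoders(d$x, c(16L, 8L),
                              sae_hyper(pretrain_epochs = 5), seed = 5)
  expect_false(identical(p1$W[[1]], p3$W[[1]]))
  expect_error(pretrain_autoencoders(d$x, c(16L, 50L)), "decreasing")
})

test_that("autoencoders compress linearly compressible data", {
  d <- make_separable(n_per_class = 40, dim = 30)
  xs <- scale(d$x)
  hy <- sae_hyper(pretrain_epochs = 2000, learning_rate = 5e-3)
  pre <- pretrain_autoencoders(xs, c(5L), hy, seed = 2)
  final_mse <- tail(pre$pretrain_log[[1]], 1)
  expect_lt(final_mse, 0.1 * mean(xs^2))
  # reconstruction loss is non-increasing overall (compare ends)
  expect_lt(final_mse, pre$pretrain_log[[1]][1])
})

test_that("fine-tuning separates separable classes and is deterministic", {
  d <- make_separable()
  xs <- scale(d$x)
  hy <- sae_hyper(pretrain_epochs = 100, finetune_epochs = 600,
                  learning_rate = 5e-3)
  pre <- pretrain_autoencoders(xs, c(16L, 8L), hy, seed = 3)
  m1 <- fine_tune_supervised(pre, xs, d$y, hy, seed = 4)
  p <- sae_predict(m1, xs)
  pred <- factor(m1$levels[max.col(p)], levels = levels(d$y))
  acc <- topoconn:::classification_metrics(pred, d$y, "A")$balanced_accuracy
  expect_gt(acc, 0.95)
  # training loss decreases
  expect_lt(tail(m1$finetune_log, 1), m1$finetune_log[1])
  m2 <- fine_tune_supervised(pre, xs, d$y, hy, seed = 4)
  expect_identical(m1$finetune_log, m2$finetune_log)
  expect_error(fine_tune_supervised(pre, xs, factor(rep("A", nrow(xs))), hy),
               "2 classes")
})

test_that("encode is a deterministic forward pass of the configured width", {
  d <- make_separable()
  hy <- sae_hyper(pretrain_epochs = 5, finetune_epochs = 5)
  pre <- pretrain_autoencoders(d$x, c(16L, 8L, 4L), hy, seed = 1)
  m <- fine_tune_supervised(pre, d$x, d$y, hy, seed = 2)
  z <- encode(m, d$x)
  expect_equal(ncol(z), 4)
  expect_equal(nrow(z), nrow(d$x))
  # identical inputs give identical codes
  x2 <- d$x[c(1, 1), ]
  z2 <- encode(m, x2)
  expect_identical(z2[1, ], z2[2, ])
  expect_error(encode(m, d$x[, 1:10]), "columns")
})

test_that("nested SVM selects the smallest C under ties and finds signal", {
  d <- make_separable(n_per_class = 25, dim = 5, gap = 8)
  fit <- train_svm_nested(d$x, d$y, seed = 3)
  # widely separable: every C achieves perfect inner accuracy; tie -> smallest
  expect_equal(fit$chosen_c, 1e-3)
  expect_equal(max(fit$inner_accuracy), 1)
  # label-independent codes: inner accuracies near chance for all C
  set.seed(9)
  znull <- matrix(rnorm(60 * 4), 60, 4)
  ynull <- factor(rep(c("A", "B"), 30))
  fit0 <- train_svm_nested(znull, ynull, seed = 3)
  expect_true(all(abs(fit0$inner_accuracy - 0.5) < 0.25))
  # deterministic under fixed seed
  fit2 <- train_svm_nested(d$x, d$y, seed = 3)
  expect_identical(fit$chosen_c, fit2$chosen_c)
})

test_that("cross-validated pipeline recovers separable structure without leakage", {
  d <- make_separable(n_per_class = 30, dim = 40, gap = 4)
  hy <- sae_hyper(pretrain_epochs = 50, finetune_epochs = 100,
                  learning_rate = 5e-3)
  cv <- cross_validate_pipeline(d$x, d$y, k_outer = 5, seed = 11,
                                layer_sizes = c(16L, 8L), hyper = hy)
  expect_gt(cv$mean[["balanced_accuracy"]], 0.9)
  # balanced-accuracy identity on every fold
  expect_equal(cv$per_fold$balanced_accuracy,
               (cv$per_fold$sensitivity + cv$per_fold$specificity) / 2,
               tolerance = 1e-12)
  # leakage audit: training-fold statistics do not depend on held-out rows
  folds <- cv$folds
  tr <- folds != 1
  st_full <- topoconn:::fit_standardizer(d$x[tr, ])
  x_damaged <- d$x
  x_damaged[!tr, ] <- 999  # corrupt the held-out fold only
  st_damaged <- topoconn:::fit_standardizer(x_damaged[tr, ])
  expect_identical(st_full, st_damaged)
  pre1 <- pretrain_autoencoders(topoconn:::apply_standardizer(st_full, d$x[tr, ]),
                                c(16L, 8L), hy,
                                seed = topoconn:::derive_seed(11, 10 + 1))
  pre2 <- pretrain_autoencoders(topoconn:::apply_standardizer(st_damaged, x_damaged[tr, ]),
                                c(16L, 8L), hy,
                                seed = topoconn:::derive_seed(11, 10 + 1))
  expect_identical(pre1$W, pre2$W)
})

test_that("chance-level data stays near chance in cross-validation", {
  set.seed(21)
  x <- matrix(rnorm(60 * 30), 60, 30)
  y <- factor(rep(c("A", "B"), 30))
  hy <- sae_hyper(pretrain_epochs = 20, finetune_epochs = 40)
  cv <- cross_validate_pipeline(x, y, k_outer = 5, seed = 2,
                                layer_sizes = c(12L, 6L), hyper = hy)
  expect_gte(cv$mean[["balanced_accuracy"]], 0.25)
  expect_lte(cv$mean[["balanced_accuracy"]], 0.75)
})

test_that("permutation test p-value follows the counting definition", {
  d <- make_separable(n_per_class = 15, dim = 20, gap = 4)
  hy <- sae_hyper(pretrain_epochs = 20, finetune_epochs = 60,
                  learning_rate = 5e-3)
  pr <- permutation_test(d$x, d$y, n_perm = 9, seed = 5, k_outer = 3,
                         layer_sizes = c(8L, 4L), hyper = hy)
  expect_length(pr$null, 9)
  expect_equal(pr$p_value, sum(pr$null >= pr$observed) / 9)
  expect_gte(pr$p_value, 0)
  expect_lte(pr$p_value, 1)
  if (pr$p_value == 0) expect_match(pr$p_label, "<")
  # boundary: observed below every permuted value -> p = 1
  fake <- pr
  fake$null <- rep(fake$observed + 1, 9)
  expect_equal(sum(fake$null >= fake$observed) / 9, 1)
  expect_error(permutation_test(d$x, d$y, n_perm = 0), "n_perm")
})

test_that("permutation p-values are approximately uniform under the null", {
  # label-independent features: p across repeated mini-runs should be uniform
  ps <- vapply(1:40, function(r) {
    x <- topoconn:::with_seed(900 + r, matrix(rnorm(24 * 20), 24, 20))
    y <- factor(rep(c("A", "B"), 12))
    pr <- permutation_test(x, y, n_perm = 24, seed = 900 + r, k_outer = 3,
                           layer_sizes = c(8L, 4L),
                           hyper = sae_hyper(5L, 10L), k_inner = 2)
    pr$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  # and the null distribution covers the observed statistic from both sides
  expect_gt(max(ps), 0.5)
  expect_lt(min(ps), 0.5)
})
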