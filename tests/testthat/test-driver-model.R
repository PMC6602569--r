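two_cluster_ds <- function(n_min = 4, n_maj = 10) {
  x <- rbind(matrix(rep(c(0, 0), n_maj) + 5, ncol = 2),
             matrix(seq_len(2 * n_min) / 10, ncol = 2))
  labeled_dataset(x, c(rep(0L, n_maj), rep(1L, n_min)))
}

test_that("smote synthesizes convex combinations and leaves the majority intact", {
  ds <- labeled_dataset(rbind(matrix(5, nrow = 10, ncol = 2),
                              matrix(c(0, 1, 0, 1), ncol = 2)),
                        c(rep(0L, 10), 1L, 1L))
  out <- smote_oversample(ds, smote_config(k_neighbors = 1, seed = 3))
  # minority target = floor(1.0 * 10) = 10 -> 8 synthetic points
  expect_equal(attr(out, "n_synthetic"), 8)
  expect_equal(sum(out$y == 1L), 10)
  # majority rows bit-identical and first
  expect_identical(out$x[1:10, ], ds$x[1:10, ])
  expect_equal(out$y[1:10], rep(0L, 10))
  # synthetic rows lie on the open segment between (0,0) and (1,1)
  synth <- out$x[13:20, , drop = FALSE]
  expect_true(all(abs(synth[, 1] - synth[, 2]) < 1e-9))
  expect_true(all(synth[, 1] >= 0 & synth[, 1] <= 1))
})

test_that("smote is a no-op when the minority already meets the target", {
  ds <- two_cluster_ds(n_min = 10, n_maj = 10)
  expect_identical(smote_oversample(ds, smote_config(seed = 1)), ds)
  half <- smote_config(target_ratio = 0.3, seed = 1)
  expect_identical(smote_oversample(two_cluster_ds(5, 10), half),
                   two_cluster_ds(5, 10))
})

test_that("smote guards its preconditions and clips k", {
  ds1 <- labeled_dataset(matrix(1:10, ncol = 2), c(0L, 0L, 0L, 0L, 1L))
  expect_error(smote_oversample(ds1, smote_config()), "at least 2")
  ds2 <- two_cluster_ds(n_min = 3, n_maj = 12)
  expect_warning(out <- smote_oversample(ds2, smote_config(k_neighbors = 5,
                                                           seed = 2)),
                 "clipped")
  expect_equal(sum(out$y == 1L), 12)
})

test_that("smote is reproducible for a seed and differs across seeds", {
  ds <- two_cluster_ds(n_min = 6, n_maj = 12)
  a <- smote_oversample(ds, smote_config(seed = 9))
  b <- smote_oversample(ds, smote_config(seed = 9))
  c <- smote_oversample(ds, smote_config(seed = 10))
  expect_identical(a, b)
  expect_false(identical(a$x, c$x))
})

test_that("training on separable data achieves perfect in-sample ranking", {
  ds <- gen_labeled_dataset(separation_spec(n_pos = 20, n_neg = 20,
                                            dprime = 8, seed = 2))
  model <- train_driver_model(ds, ensemble_config(rf_n_trees = 50,
                                                  mlp_epochs = 50, seed = 2),
                              smote_config(seed = 2))
  s <- predict(model, ds$x)
  expect_equal(roc_auc(s, ds$y)$auc, 1.0)
})

test_that("training is deterministic and serialization is bit-stable", {
  ds <- gen_labeled_dataset(separation_spec(n_pos = 15, n_neg = 60,
                                            dprime = 2, seed = 5))
  cfg <- ensemble_config(rf_n_trees = 40, mlp_epochs = 30, seed = 5)
  m1 <- train_driver_model(ds, cfg, smote_config(seed = 5))
  m2 <- train_driver_model(ds, cfg, smote_config(seed = 5))
  s1 <- predict(m1, ds$x)
  expect_identical(s1, predict(m2, ds$x))
  path <- tempfile(fileext = ".rds")
  save_model(m1, path)
  expect_identical(predict(load_model(path), ds$x), s1)
})

test_that("training rejects degenerate inputs", {
  x <- matrix(rnorm(20), ncol = 2)
  expect_error(train_driver_model(labeled_dataset(x, rep(0L, 10))),
               "both classes")
  x[1, 1] <- NA
  expect_error(train_driver_model(labeled_dataset(x, rep(c(0L, 1L), 5))),
               "finite")
})

test_that("the ensemble score is the exact mean of the two branch outputs", {
  model <- test_model()
  ds <- gen_labeled_dataset(separation_spec(n_pos = 10, n_neg = 40,
                                            dprime = 1, seed = 8))
  br <- predict_branches(model, ds$x)
  s <- predict(model, ds$x)
  expect_identical(s, (br$rf + br$mlp) / 2)
  expect_true(all(s >= 0 & s <= 1))
})

test_that("scoring enforces the feature schema", {
  model <- test_model()
  bad <- matrix(0, nrow = 1, ncol = 5)
  expect_error(predict(model, bad), "schema")
  wrong_names <- matrix(0, nrow = 1, ncol = 11,
                        dimnames = list(NULL, paste0("f", 1:11)))
  expect_error(predict(model, wrong_names), "schema")
})

test_that("the driver call is strictly greater-than the threshold", {
  expect_true(classify_driver(0.51))
  expect_false(classify_driver(0.5))
  expect_false(classify_driver(0.0))
  expect_true(classify_driver(1.0))
  expect_error(classify_driver(1.2), "\\[0, 1\\]")
  expect_error(classify_driver(-0.1), "\\[0, 1\\]")
})

test_that("default configuration carries the published hyperparameters", {
  cfg <- ensemble_config()
  expect_equal(cfg$rf_max_depth, 4L)
  expect_equal(cfg$rf_n_trees, 130L)
  expect_equal(cfg$rf_feature_fraction, 0.4)
  expect_equal(cfg$mlp_hidden, c(20L, 15L))
  expect_equal(cfg$mlp_lr, 0.1)
  expect_equal(cfg$mlp_momentum, 0.8)
  expect_equal(cfg$threshold, 0.5)
})

test_that("cross-validation folds are stratified and content-addressed", {
  ds <- gen_labeled_dataset(separation_spec(n_pos = 20, n_neg = 80,
                                            dprime = 2, seed = 6))
  f1 <- sitedriver:::cv_folds(ds, folds = 5, seed = 3)
  # stratification: every fold holds ~n_pos/5 positives
  pos_per_fold <- table(f1[ds$y == 1])
  expect_true(all(pos_per_fold == 4))
  # content-addressing: permuting rows permutes fold ids consistently
  perm <- sample(length(ds$y))
  ds_p <- labeled_dataset(ds$x[perm, ], ds$y[perm], ds$schema_version)
  f2 <- sitedriver:::cv_folds(ds_p, folds = 5, seed = 3)
  expect_equal(f2, f1[perm])
})

test_that("tuning returns the grid argmax and degenerate grids trivially", {
  ds <- gen_labeled_dataset(separation_spec(n_pos = 12, n_neg = 48,
                                            dprime = 3, seed = 9))
  one <- data.frame(rf_max_depth = 3, rf_n_trees = 20,
                    rf_feature_fraction = 0.4, mlp_epochs = 20)
  cfg <- tune_ensemble(ds, one, folds = 5, seed = 9)
  expect_equal(cfg$rf_max_depth, 3L)
  expect_equal(cfg$rf_n_trees, 20L)
  grid <- data.frame(rf_max_depth = c(2, 4), rf_n_trees = c(20, 40),
                     rf_feature_fraction = 0.4, mlp_epochs = 20)
  best <- tune_ensemble(ds, grid, folds = 5, seed = 9)
  aucs <- attr(best, "cv_auc")
  expect_length(aucs, 2)
  expect_equal(best$rf_n_trees,
               as.integer(grid$rf_n_trees[which.max(aucs)]))
  expect_error(tune_ensemble(labeled_dataset(ds$x[1:4, ], ds$y[1:4]),
                             one, folds = 10), "fewer rows")
})

test_that("cross-validation reruns SMOTE inside folds only", {
  # fold models must differ when their training rows differ, and the
  # out-of-fold score vector is complete
  ds <- gen_labeled_dataset(separation_spec(n_pos = 15, n_neg = 60,
                                            dprime = 2.5, seed = 10))
  cv <- cv_ensemble(ds, ensemble_config(rf_n_trees = 30, mlp_epochs = 20,
                                        seed = 10),
                    smote_config(seed = 10), folds = 5, seed = 10)
  expect_false(anyNA(cv$scores))
  expect_equal(sort(unique(cv$fold_id)), 1:5)
  expect_true(all(cv$scores >= 0 & cv$scores <= 1))
  expect_equal(cv$n_positive, 15)
})
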