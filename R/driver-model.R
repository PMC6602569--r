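# The driver-mutation scoring model: SMOTE class rebalancing, a random
# forest (raw features; tree splits are scale-invariant) and a multi-layer
# perceptron (standardized features), combined by an unweighted mean of the
# two class-1 probabilities. A score strictly above 0.5 calls a driver.

#' SMOTE configuration
#'
#' @param k_neighbors Number of minority nearest neighbors to interpolate
#'   with (default 5, the method's canonical value).
#' @param target_ratio Desired minority:majority ratio after resampling,
#'   in (0, 1] (default 1.0).
#' @param seed RNG seed.
#' @return A `smote_config` list.
#' @export
smote_config <- function(k_neighbors = 5, target_ratio = 1.0, seed = 1) {
  stopifnot(k_neighbors >= 1, target_ratio > 0, target_ratio <= 1)
  structure(list(k_neighbors = as.integer(k_neighbors),
                 target_ratio = target_ratio, seed = as.integer(seed)),
            class = "smote_config")
}

#' Ensemble configuration
#'
#' Defaults are the grid-search optima reported for the method: random forest
#' with maximum depth 4, 130 trees and a 0.4 feature fraction at each split;
#' perceptron with hidden layers of 20 and 15 nodes, learning rate 0.1,
#' momentum 0.8, ReLU hidden activations and a sigmoid output; branch scores
#' combined by their arithmetic mean; driver threshold 0.5 (strict).
#'
#' @param rf_max_depth,rf_n_trees,rf_feature_fraction Random-forest
#'   hyperparameters.
#' @param mlp_hidden,mlp_lr,mlp_momentum,mlp_epochs,mlp_batch Perceptron
#'   hyperparameters.
#' @param combine Combination rule; only `"mean"` is supported.
#' @param threshold Driver decision threshold (strict greater-than).
#' @param seed RNG seed for both learners.
#' @return An `ensemble_config` list.
#' @export
ensemble_config <- function(rf_max_depth = 4, rf_n_trees = 130,
                            rf_feature_fraction = 0.4,
                            mlp_hidden = c(20, 15), mlp_lr = 0.1,
                            mlp_momentum = 0.8, mlp_epochs = 200,
                            mlp_batch = 32, combine = "mean",
                            threshold = 0.5, seed = 1) {
  stopifnot(threshold > 0, threshold < 1,
            rf_feature_fraction > 0, rf_feature_fraction <= 1,
            all(mlp_hidden >= 1), combine == "mean")
  structure(list(rf_max_depth = as.integer(rf_max_depth),
                 rf_n_trees = as.integer(rf_n_trees),
                 rf_feature_fraction = rf_feature_fraction,
                 mlp_hidden = as.integer(mlp_hidden), mlp_lr = mlp_lr,
                 mlp_momentum = mlp_momentum,
                 mlp_epochs = as.integer(mlp_epochs),
                 mlp_batch = as.integer(mlp_batch), combine = combine,
                 threshold = threshold, seed = as.integer(seed)),
            class = "ensemble_config")
}

#' Construct a labeled dataset
#'
#' @param x Feature matrix.
#' @param y 0/1 labels (1 = driver).
#' @param schema_version Schema version string.
#' @return A `labeled_dataset`.
#' @export
labeled_dataset <- function(x, y, schema_version = "v1") {
  x <- as.matrix(x)
  y <- as.integer(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0L, 1L)))
  structure(list(x = x, y = y, schema_version = schema_version),
            class = "labeled_dataset")
}

#' SMOTE oversampling of the minority class
#'
#' Generates synthetic minority points by interpolation: each synthetic row is
#' `x + u * (x_nn - x)` for a minority row `x`, one of its `k` nearest
#' minority neighbors `x_nn` (Euclidean distance) and `u` uniform on \[0,1\].
#' Majority rows come first and are untouched; original minority rows follow;
#' synthetic rows are appended until the minority count reaches
#' `floor(target_ratio * majority)`.
#'
#' @param ds A [labeled_dataset()].
#' @param cfg A [smote_config()].
#' @return A resampled `labeled_dataset`; unchanged if the minority class is
#'   already at or above the target ratio.
#' @export
smote_oversample <- function(ds, cfg = smote_config()) {
  stopifnot(inherits(ds, "labeled_dataset"))
  tab <- c(sum(ds$y == 0L), sum(ds$y == 1L))
  min_lab <- if (tab[2] <= tab[1]) 1L else 0L
  maj_lab <- 1L - min_lab
  n_min <- sum(ds$y == min_lab)
  n_maj <- sum(ds$y == maj_lab)
  if (n_min < 2) stop("minority class must have at least 2 members", call. = FALSE)
  n_target <- floor(cfg$target_ratio * n_maj)
  if (n_min >= n_target) return(ds)
  k <- cfg$k_neighbors
  if (k >= n_min) {
    warning(sprintf("k_neighbors clipped from %d to %d (minority size)",
                    k, n_min - 1L), call. = FALSE)
    k <- n_min - 1L
  }
  x_min <- ds$x[ds$y == min_lab, , drop = FALSE]
  x_maj <- ds$x[ds$y == maj_lab, , drop = FALSE]
  d <- as.matrix(stats::dist(x_min))
  nn_idx <- do.call(rbind, lapply(seq_len(n_min),
                                  function(i) order(d[i, ])[2:(k + 1)]))
  n_synth <- n_target - n_min
  synth <- with_seed(cfg$seed, {
    out <- matrix(NA_real_, nrow = n_synth, ncol = ncol(ds$x))
    for (i in seq_len(n_synth)) {
      base <- sample.int(n_min, 1)
      nb <- nn_idx[base, sample.int(k, 1)]
      u <- stats::runif(1)
      out[i, ] <- x_min[base, ] + u * (x_min[nb, ] - x_min[base, ])
    }
    out
  })
  colnames(synth) <- colnames(ds$x)
  x_new <- rbind(x_maj, x_min, synth)
  y_new <- c(rep(maj_lab, n_maj), rep(min_lab, n_min + n_synth))
  out <- labeled_dataset(x_new, y_new, ds$schema_version)
  attr(out, "n_synthetic") <- n_synth
  out
}

#' Train the driver-scoring ensemble
#'
#' SMOTE is applied to the training data, standardization parameters are
#' fitted on the post-SMOTE rows, the random forest is fitted on raw features
#' and the perceptron on standardized features. With a fixed seed the whole
#' procedure is reproducible.
#'
#' @param ds A [labeled_dataset()] with both classes present.
#' @param ecfg An [ensemble_config()].
#' @param scfg A [smote_config()].
#' @return A `driver_model`.
#' @export
train_driver_model <- function(ds, ecfg = ensemble_config(),
                               scfg = smote_config()) {
  stopifnot(inherits(ds, "labeled_dataset"))
  if (length(unique(ds$y)) < 2) stop("training data must contain both classes",
                                     call. = FALSE)
  if (!all(is.finite(ds$x))) stop("non-finite feature values", call. = FALSE)
  bal <- smote_oversample(ds, scfg)
  std <- standardize_fit(bal$x)
  p <- ncol(bal$x)
  mtry <- max(1L, floor(ecfg$rf_feature_fraction * p))
  dat <- as.data.frame(bal$x)
  dat$.label <- factor(bal$y, levels = c(0, 1))
  rf <- ranger::ranger(dependent.variable.name = ".label", data = dat,
                       num.trees = ecfg$rf_n_trees,
                       max.depth = ecfg$rf_max_depth, mtry = mtry,
                       probability = TRUE, seed = ecfg$seed, num.threads = 1,
                       verbose = FALSE)
  # The perceptron's early-stopping loss is monitored on a stratified 10%
  # hold-out of the raw rows, excluded from its SMOTE run and its training
  # set: monitoring rows that SMOTE has interpolated (or that the net has
  # seen) lets memorization masquerade as a loss plateau, and the selected
  # net then pushes out-of-sample points to saturated scores.
  n0 <- sum(ds$y == 0L)
  n1 <- sum(ds$y == 1L)
  if (n0 >= 10 && n1 >= 10) {
    mon_idx <- with_seed(ecfg$seed, {
      unlist(lapply(c(0L, 1L), function(cls) {
        i_cls <- which(ds$y == cls)
        sample(i_cls, max(1L, floor(0.1 * length(i_cls))))
      }))
    })
    fit_ds <- labeled_dataset(ds$x[-mon_idx, , drop = FALSE], ds$y[-mon_idx],
                              ds$schema_version)
    scfg_m <- scfg
    scfg_m$seed <- scfg$seed + 1L
    bal_m <- smote_oversample(fit_ds, scfg_m)
    mlp <- mlp_fit(standardize_apply(bal_m$x, std), bal_m$y,
                   hidden = ecfg$mlp_hidden, lr = ecfg$mlp_lr,
                   momentum = ecfg$mlp_momentum, epochs = ecfg$mlp_epochs,
                   batch = ecfg$mlp_batch,
                   x_val = standardize_apply(ds$x[mon_idx, , drop = FALSE], std),
                   y_val = ds$y[mon_idx], seed = ecfg$seed)
  } else {
    mlp <- mlp_fit(standardize_apply(bal$x, std), bal$y,
                   hidden = ecfg$mlp_hidden, lr = ecfg$mlp_lr,
                   momentum = ecfg$mlp_momentum, epochs = ecfg$mlp_epochs,
                   batch = ecfg$mlp_batch, seed = ecfg$seed)
  }
  structure(list(rf = rf, mlp = mlp, standardization = std, config = ecfg,
                 smote = scfg, schema_version = ds$schema_version),
            class = "driver_model")
}

check_schema <- function(model, x) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
       else as.matrix(x)
  want <- names(model$standardization$means)
  if (!is.null(colnames(x))) {
    if (!identical(colnames(x), want)) {
      stop("feature schema mismatch: expected columns ",
           paste(want, collapse = ", "), call. = FALSE)
    }
  } else if (ncol(x) != length(want)) {
    stop("feature schema mismatch: expected ", length(want), " features",
         call. = FALSE)
  } else {
    colnames(x) <- want
  }
  x
}

#' Branch outputs of the ensemble
#'
#' @param model A `driver_model`.
#' @param x Feature matrix or single vector (raw, schema-ordered).
#' @return list(rf, mlp): the two class-1 probability vectors.
#' @export
predict_branches <- function(model, x) {
  stopifnot(inherits(model, "driver_model"))
  x <- check_schema(model, x)
  rf_p <- stats::predict(model$rf, data = as.data.frame(x),
                         num.threads = 1)$predictions[, "1"]
  mlp_p <- predict(model$mlp, standardize_apply(x, model$standardization))
  list(rf = unname(rf_p), mlp = unname(mlp_p))
}

#' Score mutations with the ensemble
#'
#' @param object A `driver_model`.
#' @param x Raw feature matrix (schema-ordered columns) or single vector.
#' @param ... Unused.
#' @return Numeric scores in \[0, 1\], the mean of the two branch outputs.
#' @export
predict.driver_model <- function(object, x, ...) {
  br <- predict_branches(object, x)
  (br$rf + br$mlp) / 2
}

#' Driver decision at a threshold
#'
#' A mutation is called a driver when its score strictly exceeds the
#' threshold; a score of exactly 0.5 is not a driver.
#'
#' @param score Numeric scores in \[0, 1\].
#' @param threshold Decision threshold (default 0.5).
#' @return Logical vector.
#' @export
classify_driver <- function(score, threshold = 0.5) {
  if (any(!is.finite(score)) || any(score < 0 | score > 1)) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  score > threshold
}

#' Save / load a trained model
#'
#' The bundle contains both learner states, the standardization parameters,
#' the configurations and the schema version; reloading reproduces scores
#' bit-for-bit.
#'
#' @param model A `driver_model`.
#' @param path File path.
#' @return `save_model`: invisibly the path; `load_model`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "driver_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  model <- readRDS(path)
  if (!inherits(model, "driver_model")) {
    stop("not a driver_model bundle: ", path, call. = FALSE)
  }
  model
}

# Fold assignment that depends on row content, not row order: rows are put in
# a canonical (lexicographic) order within each class stratum before the
# seeded shuffle, so permuting the input rows permutes fold ids consistently.
cv_folds <- function(ds, folds = 10, seed = 1) {
  n <- length(ds$y)
  if (n < folds) stop("fewer rows than folds", call. = FALSE)
  fold_id <- integer(n)
  for (lab in unique(ds$y)) {
    idx <- which(ds$y == lab)
    canon <- idx[do.call(order, as.data.frame(ds$x[idx, , drop = FALSE]))]
    ids <- with_seed(seed + lab, {
      sample(rep_len(seq_len(folds), length(canon)))
    })
    fold_id[canon] <- ids
  }
  fold_id
}

#' Cross-validated evaluation of the ensemble
#'
#' Stratified k-fold cross-validation with SMOTE re-run inside each training
#' fold (synthetic points never cross a fold boundary). Returns pooled
#' out-of-fold scores and per-fold AUCs.
#'
#' @param ds A [labeled_dataset()].
#' @param ecfg,scfg Configurations; the SMOTE seed is offset per fold.
#' @param folds Number of folds (default 10).
#' @param seed Seed controlling fold assignment.
#' @return list(scores, fold_id, auc_per_fold, auc_pooled, sensitivity,
#'   detected, n_positive).
#' @export
cv_ensemble <- function(ds, ecfg = ensemble_config(), scfg = smote_config(),
                        folds = 10, seed = 1) {
  fold_id <- cv_folds(ds, folds, seed)
  scores <- rep(NA_real_, length(ds$y))
  auc_per_fold <- rep(NA_real_, folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    te <- fold_id == f
    scfg_f <- scfg
    scfg_f$seed <- scfg$seed + f
    ecfg_f <- ecfg
    ecfg_f$seed <- ecfg$seed + f
    model <- train_driver_model(
      labeled_dataset(ds$x[tr, , drop = FALSE], ds$y[tr], ds$schema_version),
      ecfg_f, scfg_f)
    scores[te] <- predict(model, ds$x[te, , drop = FALSE])
    if (length(unique(ds$y[te])) == 2) {
      auc_per_fold[f] <- roc_auc(scores[te], ds$y[te])$auc
    }
  }
  pooled <- roc_auc(scores, ds$y)
  sens <- sensitivity_at(scores, ds$y, ecfg$threshold)
  list(scores = scores, fold_id = fold_id, auc_per_fold = auc_per_fold,
       auc_pooled = pooled$auc, sensitivity = sens$detected / sens$total,
       detected = sens$detected, n_positive = sens$total)
}

#' Grid-search hyperparameter tuning
#'
#' Evaluates each grid point by stratified cross-validated AUC (SMOTE inside
#' training folds only) and returns the configuration maximizing the mean
#' per-fold AUC. The grid is a data.frame whose columns name
#' [ensemble_config()] arguments (e.g. rf_max_depth, rf_n_trees,
#' rf_feature_fraction).
#'
#' @param ds A [labeled_dataset()].
#' @param grid data.frame of hyperparameter combinations.
#' @param folds Number of folds (default 10).
#' @param seed Fold-assignment seed.
#' @param scfg SMOTE configuration.
#' @return The winning `ensemble_config`, with attribute `cv_auc` (vector of
#'   mean CV AUCs per grid row).
#' @export
tune_ensemble <- function(ds, grid, folds = 10, seed = 1,
                          scfg = smote_config()) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1)
  if (length(ds$y) < folds) stop("fewer rows than folds", call. = FALSE)
  aucs <- rep(NA_real_, nrow(grid))
  cfgs <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    args <- as.list(grid[g, , drop = FALSE])
    args <- lapply(args, unlist)
    cfg <- do.call(ensemble_config, c(args, list(seed = seed)))
    cv <- cv_ensemble(ds, cfg, scfg, folds = folds, seed = seed)
    aucs[g] <- mean(cv$auc_per_fold, na.rm = TRUE)
    cfgs[[g]] <- cfg
  }
  best <- cfgs[[which.max(aucs)]]
  attr(best, "cv_auc") <- aucs
  best
}
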