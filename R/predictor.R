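## Stacking ensemble predicting BRDF parameters from phenotypic traits:
## z-score standardization, recursive feature elimination to 5 of 9 features,
## SVR / random-forest / gradient-boosting base learners tuned by 10-fold CV
## grid search, and a linear-regression meta-learner trained on out-of-fold
## base predictions. All randomness is seeded; test rows never touch the
## standardization statistics, the feature selection or the grids.

#' The nine phenotypic predictor columns
#' @export
el_feature_names <- c("thickness_mm", "slw_g_m2", "chl_a", "chl_b", "car",
                      "chl_ab", "chl_ratio", "rho", "wavelength_nm")

#' Z-score standardization with a reusable transform
#'
#' Centers and scales each column to zero mean and unit variance, returning
#' the statistics so the identical transform can be applied to new (test)
#' data.
#'
#' @param X Numeric data frame or matrix.
#' @param center,scale Optional precomputed statistics (training-set values)
#'   to apply instead of computing from `X`.
#' @return List with `X` (standardized data frame), `center`, `scale`.
#' @export
standardize <- function(X, center = NULL, scale = NULL) {
  X <- as.data.frame(X)
  if (is.null(center)) {
    center <- vapply(X, mean, numeric(1))
    scale <- vapply(X, stats::sd, numeric(1))
    zero <- scale < 1e-12
    if (any(zero)) {
      stop("zero-variance column(s): ",
           paste(names(X)[zero], collapse = ", "), call. = FALSE)
    }
  }
  Xs <- as.data.frame(mapply(function(col, m, s) (col - m) / s,
                             X, center[names(X)], scale[names(X)],
                             SIMPLIFY = FALSE))
  list(X = Xs, center = center, scale = scale)
}

#' Recursive feature elimination by random-forest importance
#'
#' Iteratively fits a random forest and drops the least important feature
#' until `n_keep` remain. Deterministic for a fixed seed.
#'
#' @param X Feature data frame.
#' @param y Target vector.
#' @param n_keep Number of features to retain (default 5; must be fewer than
#'   the number of columns).
#' @param seed Integer seed.
#' @param ntree Trees per forest.
#' @return Character vector of `n_keep` retained feature names, in original
#'   column order.
#' @export
rfe_select <- function(X, y, n_keep = 5, seed = 1, ntree = 300) {
  X <- as.data.frame(X)
  if (n_keep >= ncol(X)) {
    stop("n_keep must be smaller than the number of features", call. = FALSE)
  }
  current <- names(X)
  it <- 0L
  while (length(current) > n_keep) {
    set.seed(seed + it)
    rf <- randomForest::randomForest(X[current], y, ntree = ntree)
    imp <- randomForest::importance(rf)[, 1]
    current <- setdiff(current, names(which.min(imp)))
    it <- it + 1L
  }
  names(X)[names(X) %in% current]
}

#' Hyperparameter grids for the base learners
#'
#' Small published defaults: SV penalty `cost` in \{0.1, 1, 10\}; forest size
#' in \{100, 300\}; boosting tree depth in \{2, 3\}.
#' @export
el_grids <- function() {
  list(svr = expand.grid(cost = c(0.1, 1, 10)),
       rfr = expand.grid(ntree = c(100, 300)),
       gbrt = expand.grid(max_depth = c(2, 3)))
}

.fit_base <- function(kind, X, y, hp, seed) {
  set.seed(seed)
  switch(kind,
         svr = e1071::svm(x = as.matrix(X), y = y, type = "eps-regression",
                          kernel = "radial", cost = hp$cost),
         rfr = randomForest::randomForest(X, y, ntree = hp$ntree),
         gbrt = xgboost::xgb.train(
           data = xgboost::xgb.DMatrix(as.matrix(X), label = y,
                                       nthread = 1),
           nrounds = 150,
           params = list(max_depth = hp$max_depth, eta = 0.1,
                         objective = "reg:squarederror", nthread = 1)))
}

.predict_base <- function(kind, model, X) {
  switch(kind,
         svr = as.numeric(stats::predict(model, as.matrix(X))),
         rfr = as.numeric(stats::predict(model, X)),
         gbrt = as.numeric(stats::predict(model,
                                          xgboost::xgb.DMatrix(as.matrix(X),
                                                               nthread = 1))))
}

## 10-fold CV MSE for one (learner, hyperparameter) pair over fixed folds.
.cv_mse <- function(kind, X, y, hp, folds, seed) {
  errs <- vapply(seq_len(max(folds)), function(f) {
    tr <- folds != f
    m <- .fit_base(kind, X[tr, , drop = FALSE], y[tr], hp, seed + f)
    mean((.predict_base(kind, m, X[!tr, , drop = FALSE]) - y[!tr])^2)
  }, numeric(1))
  mean(errs)
}

#' Train the stacking ensemble for one BRDF parameter
#'
#' Full pipeline: an 8:2 train/test split; z-score standardization fitted on
#' the training rows; recursive feature elimination to `n_keep` features;
#' per-base-learner grid search minimizing `cv_folds`-fold cross-validated
#' MSE on the training split; a linear-regression meta-learner fitted on
#' out-of-fold base predictions (so the meta-learner never sees a base
#' learner's in-sample fit); base learners refit on the full training split;
#' evaluation (MSE, R-squared) on the held-out 20%.
#'
#' @param data Data frame holding the feature columns and the target.
#' @param target Target column name: `"sigma"`, `"k"` or `"n"`.
#' @param features Candidate feature columns (default [el_feature_names]).
#' @param split_seed Seed for the 8:2 split (default 42).
#' @param cv_folds Cross-validation folds (default 10).
#' @param grids Hyperparameter grids, see [el_grids()].
#' @param n_keep Features retained by RFE (default 5).
#' @param learner_seed Base seed for all stochastic learners.
#' @return Object of class `el_model` with the transform, selected features,
#'   fitted base learners, meta-learner, and an evaluation report
#'   (`report$mse`, `report$r_squared`, split sizes, per-base test MSE,
#'   CV tables).
#' @examples
#' \donttest{
#' d <- synth_trait_dataset(n_samples = 100, seed = 1)
#' m <- train_el(d, "sigma", cv_folds = 5)
#' m$report$r_squared
#' }
#' @export
train_el <- function(data, target = c("sigma", "k", "n"),
                     features = el_feature_names, split_seed = 42,
                     cv_folds = 10, grids = el_grids(), n_keep = 5,
                     learner_seed = 1) {
  target <- match.arg(target)
  data <- as.data.frame(data)
  stopifnot(all(features %in% names(data)), target %in% names(data))
  n <- nrow(data)
  if (n < 50) stop("need at least 50 samples", call. = FALSE)
  if (floor(0.8 * n) < 2 * cv_folds) {
    stop("too few samples per fold", call. = FALSE)
  }
  set.seed(split_seed)
  test_idx <- sort(sample.int(n, round(0.2 * n)))
  train_idx <- setdiff(seq_len(n), test_idx)
  Xtr_raw <- data[train_idx, features, drop = FALSE]
  ytr <- data[train_idx, target]
  Xte_raw <- data[test_idx, features, drop = FALSE]
  yte <- data[test_idx, target]

  std <- standardize(Xtr_raw)
  Xtr <- std$X
  Xte <- standardize(Xte_raw, center = std$center, scale = std$scale)$X

  selected <- rfe_select(Xtr, ytr, n_keep = n_keep, seed = learner_seed)
  Xtr <- Xtr[selected]
  Xte <- Xte[selected]

  set.seed(split_seed + 1)
  folds <- sample(rep_len(seq_len(cv_folds), length(train_idx)))

  kinds <- c("svr", "rfr", "gbrt")
  cv_tables <- list()
  best_hp <- list()
  for (kind in kinds) {
    grid <- grids[[kind]]
    mse <- vapply(seq_len(nrow(grid)), function(g) {
      .cv_mse(kind, Xtr, ytr, grid[g, , drop = FALSE], folds,
              learner_seed * 100)
    }, numeric(1))
    cv_tables[[kind]] <- cbind(grid, cv_mse = mse)
    best_hp[[kind]] <- grid[which.min(mse), , drop = FALSE]
  }

  # out-of-fold base predictions for the meta-learner
  oof <- matrix(NA_real_, nrow = length(train_idx), ncol = length(kinds),
                dimnames = list(NULL, kinds))
  for (kind in kinds) {
    for (f in seq_len(cv_folds)) {
      tr <- folds != f
      m <- .fit_base(kind, Xtr[tr, , drop = FALSE], ytr[tr], best_hp[[kind]],
                     learner_seed * 100 + f)
      oof[!tr, kind] <- .predict_base(kind, m, Xtr[!tr, , drop = FALSE])
    }
  }
  meta_df <- as.data.frame(oof)
  meta_df$y <- ytr
  meta <- stats::lm(y ~ svr + rfr + gbrt, data = meta_df)

  base_models <- lapply(stats::setNames(kinds, kinds), function(kind) {
    .fit_base(kind, Xtr, ytr, best_hp[[kind]], learner_seed * 1000)
  })
  base_test <- vapply(kinds, function(kind) {
    .predict_base(kind, base_models[[kind]], Xte)
  }, numeric(length(test_idx)))
  if (is.null(dim(base_test))) base_test <- matrix(base_test, nrow = length(test_idx))
  colnames(base_test) <- kinds
  pred_te <- as.numeric(stats::predict(meta, as.data.frame(base_test)))
  gof <- goodness_of_fit(pred_te, yte)
  base_mse <- colMeans((base_test - yte)^2)

  structure(list(
    target = target, selected_features = selected,
    center = std$center, scale = std$scale,
    base_learners = base_models, best_hyperparams = best_hp,
    meta_learner = meta, cv_tables = cv_tables,
    report = list(mse = mean((pred_te - yte)^2),
                  r_squared = gof$r_squared,
                  split = c(train_n = length(train_idx),
                            test_n = length(test_idx)),
                  cv_folds = cv_folds,
                  base_test_mse = base_mse),
    seeds = c(split = split_seed, learner = learner_seed),
    test_idx = test_idx,
    test_predictions = pred_te, test_observed = yte
  ), class = "el_model")
}

#' @export
print.el_model <- function(x, ...) {
  cat(sprintf("Stacking ensemble for BRDF parameter '%s'\n", x$target))
  cat("  features:", paste(x$selected_features, collapse = ", "), "\n")
  cat(sprintf("  split %d:%d, %d-fold CV grid search\n",
              x$report$split["train_n"], x$report$split["test_n"],
              x$report$cv_folds))
  cat(sprintf("  held-out MSE = %.5f, R^2 = %.4f\n",
              x$report$mse, x$report$r_squared))
  invisible(x)
}

#' @export
summary.el_model <- function(object, ...) {
  print(object)
  cat("  meta-learner coefficients:\n")
  print(stats::coef(object$meta_learner))
  cat("  base-learner held-out MSE:\n")
  print(object$report$base_test_mse)
  invisible(object)
}

#' Predict a BRDF parameter from traits
#'
#' @param object An `el_model`.
#' @param newdata Data frame containing the nine feature columns (raw scale;
#'   the training standardization is applied internally).
#' @param ... Unused.
#' @return Predicted parameter values.
#' @export
predict.el_model <- function(object, newdata, ...) {
  feats <- names(object$center)
  missing <- setdiff(feats, names(newdata))
  if (length(missing)) {
    stop("newdata missing feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  Xs <- standardize(newdata[feats], center = object$center,
                    scale = object$scale)$X[object$selected_features]
  base <- vapply(names(object$base_learners), function(kind) {
    .predict_base(kind, object$base_learners[[kind]], Xs)
  }, numeric(nrow(Xs)))
  if (is.null(dim(base))) base <- matrix(base, nrow = nrow(Xs),
                                         dimnames = list(NULL, names(object$base_learners)))
  as.numeric(stats::predict(object$meta_learner, as.data.frame(base)))
}

#' Random-forest feature importances of a fitted ensemble
#'
#' Normalized importances (summing to 1) of the random-forest base learner,
#' in descending order.
#'
#' @param model An `el_model` with a fitted random-forest base learner.
#' @return Named numeric vector of importances.
#' @export
feature_importance <- function(model) {
  if (!inherits(model, "el_model") || is.null(model$base_learners$rfr)) {
    stop("model has no fitted random-forest base learner", call. = FALSE)
  }
  imp <- randomForest::importance(model$base_learners$rfr)[, 1]
  imp <- imp / sum(imp)
  sort(imp, decreasing = TRUE)
}
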