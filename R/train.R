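# Gradient-boosted tree models of the thrombolysis decision: feature
# encoding, the k-fold / all-data / holdout training variants, and the
# accuracy surface.

#' Model configuration
#'
#' Hyperparameter and variant settings for the boosted-tree classifier.
#' Defaults use shallow trees (depth 3, 150 rounds, learning rate 0.3),
#' chosen for faithful recovery of the underlying log-odds effects: the
#' decision process being modelled is dominated by additive effects, so
#' shallow ensembles lose no accuracy, enough boosting rounds are needed
#' for the fitted margins (and hence SHAP fold changes) to reach the true
#' effect magnitudes, and shallow trees keep the pairwise SHAP interaction
#' decomposition fast.
#'
#' @param variant One of `"kfold"`, `"all_data"`, `"holdout"`.
#' @param n_folds Folds for the k-fold variant (>= 2).
#' @param holdout_size Held-out cohort size for the holdout variant.
#' @param nrounds,max_depth,eta,subsample xgboost hyperparameters.
#' @param seed Seed for fold assignment, holdout draw and tree fitting.
#' @return Object of class `model_config`.
#' @export
model_config <- function(variant = c("kfold", "all_data", "holdout"),
                         n_folds = 5, holdout_size = 10000,
                         nrounds = 150, max_depth = 3, eta = 0.3,
                         subsample = 1, seed = 42) {
  variant <- match.arg(variant)
  if (n_folds < 2) stop("config error: `n_folds` must be >= 2")
  cfg <- list(variant = variant, n_folds = as.integer(n_folds),
              holdout_size = as.integer(holdout_size),
              nrounds = as.integer(nrounds), max_depth = as.integer(max_depth),
              eta = eta, subsample = subsample, seed = as.integer(seed))
  class(cfg) <- "model_config"
  cfg
}

#' Encode a patient table into a model matrix
#'
#' Numeric features pass through; `stroke_team` becomes one indicator
#' column per team (`team::<id>`), so a patient can later be counterfactually
#' "moved" to another hospital by rewriting the indicator block. The
#' returned encoding map makes the transformation invertible.
#'
#' @param table Patient table (label column, if present, is dropped).
#' @param encoding Optional existing encoding (for transform-time use);
#'   unseen teams then raise an error.
#' @return List with `x` (numeric matrix), `encoding` (class `team_encoding`:
#'   team levels and column names) and `label` (the label vector or NULL).
#' @export
encode_features <- function(table, encoding = NULL) {
  label <- table[["thrombolysis"]]
  feats <- setdiff(names(table), "thrombolysis")
  if (is.null(encoding)) {
    teams <- sort(unique(as.character(table$stroke_team)))
    encoding <- structure(
      list(teams = teams,
           numeric_features = setdiff(feats, "stroke_team")),
      class = "team_encoding")
  } else {
    unseen <- setdiff(unique(as.character(table$stroke_team)), encoding$teams)
    if (length(unseen)) {
      stop("encoding error: unseen stroke team(s) ",
           paste(unseen, collapse = ", "))
    }
  }
  num <- as.matrix(table[, encoding$numeric_features, drop = FALSE])
  storage.mode(num) <- "double"
  onehot <- matrix(0, nrow(table), length(encoding$teams),
                   dimnames = list(NULL, paste0("team::", encoding$teams)))
  idx <- match(as.character(table$stroke_team), encoding$teams)
  onehot[cbind(seq_len(nrow(table)), idx)] <- 1
  list(x = cbind(num, onehot), encoding = encoding, label = label)
}

#' Recover the patient table columns from an encoded matrix
#'
#' Inverse of [encode_features()] (up to column order).
#'
#' @param x Encoded matrix.
#' @param encoding The `team_encoding` used to build it.
#' @return Data.frame with the numeric features and `stroke_team`.
#' @export
decode_features <- function(x, encoding) {
  out <- as.data.frame(x[, encoding$numeric_features, drop = FALSE])
  onehot <- x[, paste0("team::", encoding$teams), drop = FALSE]
  out$stroke_team <- encoding$teams[max.col(onehot)]
  out
}

#' Rewrite the hospital indicator block of an encoded matrix
#'
#' Sets every row's team indicators to the given team — the elementary move
#' of the counterfactual cohort analysis.
#'
#' @param x Encoded matrix.
#' @param team Team identifier (must be in the encoding).
#' @param encoding The `team_encoding`.
#' @return The rewritten matrix.
#' @export
set_team <- function(x, team, encoding) {
  if (!team %in% encoding$teams) {
    stop("encoding error: unseen stroke team ", team)
  }
  cols <- paste0("team::", encoding$teams)
  x[, cols] <- 0
  x[, paste0("team::", team)] <- 1
  x
}

# subset encoded columns to a set of reporting features
feature_columns <- function(encoding, features) {
  unlist(lapply(features, function(f) {
    if (f == "stroke_team") paste0("team::", encoding$teams) else f
  }))
}

xgb_params <- function(config) {
  list(objective = "binary:logistic", max_depth = config$max_depth,
       eta = config$eta, subsample = config$subsample, nthread = 1,
       seed = config$seed)
}

fit_booster <- function(x, y, config) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  xgboost::xgb.train(params = xgb_params(config), data = dtrain,
                     nrounds = config$nrounds, verbose = 0)
}

new_tv_model <- function(booster, encoding, config, train_idx, feature_names) {
  structure(list(booster = booster, encoding = encoding, config = config,
                 feature_names = feature_names, train_idx = train_idx),
            class = "tv_model")
}

#' Predict thrombolysis probability (or raw log-odds margin)
#'
#' @param object A fitted `tv_model`.
#' @param newdata Patient table or pre-encoded matrix.
#' @param type `"prob"` or `"margin"` (raw log-odds).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.tv_model <- function(object, newdata, type = c("prob", "margin"), ...) {
  type <- match.arg(type)
  x <- if (is.matrix(newdata)) newdata else
    encode_features(newdata, object$encoding)$x
  x <- x[, object$feature_names, drop = FALSE]
  stats::predict(object$booster, x, outputmargin = (type == "margin"))
}

#' @export
print.tv_model <- function(x, ...) {
  cat("<tv_model> boosted-tree thrombolysis classifier\n")
  cat("  teams:", length(x$encoding$teams),
      " rounds:", x$config$nrounds, " depth:", x$config$max_depth, "\n")
  invisible(x)
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Fit the k-fold cross-validated model
#'
#' Folds are stratified on the label; each row is predicted exactly once
#' out-of-fold, and the accuracy surface is computed on the pooled
#' out-of-fold predictions.
#'
#' @param table Labelled patient table.
#' @param config A [model_config()].
#' @param features Optional subset of reporting features to train on
#'   (e.g. dropping `"stroke_team"` trains a model blind to hospital
#'   identity); defaults to all features in the table.
#' @return List with `models` (one `tv_model` per fold), `fold` (fold id per
#'   row), `oof_prob` (out-of-fold predictions) and `metrics` (a
#'   [metrics_report()]).
#' @export
fit_kfold <- function(table, config = model_config("kfold"), features = NULL) {
  validate_patient_table(table)
  enc <- encode_features(table)
  if (!is.null(features)) {
    enc$x <- enc$x[, feature_columns(enc$encoding, features), drop = FALSE]
  }
  y <- enc$label
  fold <- stratified_folds(y, config$n_folds, config$seed)
  if (any(tapply(y, fold, function(v) length(unique(v))) < 2)) {
    stop("stratification error: a fold contains a single class")
  }
  models <- vector("list", config$n_folds)
  oof <- numeric(length(y))
  for (k in seq_len(config$n_folds)) {
    tr <- fold != k
    booster <- fit_booster(enc$x[tr, , drop = FALSE], y[tr], config)
    models[[k]] <- new_tv_model(booster, enc$encoding, config, which(tr),
                                colnames(enc$x))
    oof[!tr] <- stats::predict(booster, enc$x[!tr, , drop = FALSE])
  }
  list(models = models, fold = fold, oof_prob = oof,
       metrics = metrics_report(oof, y, table))
}

#' Fit the all-data model
#'
#' A single model trained on every patient, used for the SHAP analysis of
#' feature effects and hospital propensity.
#'
#' @inheritParams fit_kfold
#' @return A `tv_model`.
#' @export
fit_all_data <- function(table, config = model_config("all_data"),
                         features = NULL) {
  validate_patient_table(table)
  enc <- encode_features(table)
  if (!is.null(features)) {
    enc$x <- enc$x[, feature_columns(enc$encoding, features), drop = FALSE]
  }
  booster <- fit_booster(enc$x, enc$label, config)
  new_tv_model(booster, enc$encoding, config, seq_len(nrow(table)),
               colnames(enc$x))
}

#' Fit the holdout model and return the held-out cohort
#'
#' Trains on all rows except a label-stratified held-out cohort, returned
#' with its original (un-encoded) features so its hospital assignment can be
#' rewritten in the counterfactual analysis.
#'
#' @inheritParams fit_kfold
#' @return List with `model` (a `tv_model`), `cohort` (held-out rows,
#'   original features) and `holdout_idx` (their row indices in `table`).
#' @export
fit_holdout <- function(table, config = model_config("holdout")) {
  validate_patient_table(table)
  n <- nrow(table)
  if (config$holdout_size >= n) {
    stop("config error: `holdout_size` must be smaller than the table")
  }
  y <- table$thrombolysis
  set.seed(config$seed)
  prop <- config$holdout_size / n
  hold <- unlist(lapply(split(seq_len(n), y), function(idx) {
    sample(idx, round(length(idx) * prop))
  }), use.names = FALSE)
  hold <- sort(hold)
  train <- setdiff(seq_len(n), hold)
  if (length(unique(y[train])) < 2) {
    stop("config error: training remainder has a single class")
  }
  enc <- encode_features(table)  # encoding over all teams
  booster <- fit_booster(enc$x[train, , drop = FALSE], y[train], config)
  list(model = new_tv_model(booster, enc$encoding, config, train,
                            colnames(enc$x)),
       cohort = table[hold, , drop = FALSE],
       holdout_idx = hold)
}
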