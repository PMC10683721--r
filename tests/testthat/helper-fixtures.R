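# Shared fixtures, memoised so expensive fits happen once per test run.

fix_env <- new.env(parent = emptyenv())

# 8 hospitals x ~250 patients: the small workhorse dataset
small_dataset <- function() {
  if (is.null(fix_env$ds)) {
    fix_env$ds <- generate_dataset(
      generator_config(n_hospitals = 8, patients_per_hospital = 250, seed = 7))
  }
  fix_env$ds
}

small_config <- function(variant = "all_data", nrounds = 100, ...) {
  model_config(variant, nrounds = nrounds, max_depth = 3, seed = 7, ...)
}

small_all_fit <- function() {
  if (is.null(fix_env$fit)) {
    fix_env$fit <- fit_all_data(small_dataset()$patients, small_config())
  }
  fix_env$fit
}

small_shap <- function() {
  if (is.null(fix_env$shap)) {
    fix_env$shap <- compute_shap(small_all_fit(), small_dataset()$patients)
  }
  fix_env$shap
}

small_tensor <- function() {
  if (is.null(fix_env$tensor)) {
    fix_env$tensor <- compute_interactions(small_all_fit(),
                                           small_dataset()$patients)
  }
  fix_env$tensor
}

small_holdout <- function() {
  if (is.null(fix_env$holdout)) {
    fix_env$holdout <- fit_holdout(
      small_dataset()$patients,
      small_config("holdout", holdout_size = 400))
  }
  fix_env$holdout
}

# Small squared-error booster on its own training data: margin output and
# unit hessian, so stored node covers equal background row counts and the
# coalition oracle is exactly comparable.
toy_margin_booster <- function(n = 50, p = 4, depth = 3, nrounds = 10,
                               seed = 1, interacting = TRUE) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- x[, 1] + stats::rnorm(n) * 0.2
  if (interacting && p >= 3) y <- y + 0.8 * x[, 2] * x[, 3]
  booster <- xgboost::xgb.train(
    params = list(objective = "reg:squarederror", max_depth = depth,
                  eta = 0.3, nthread = 1, tree_method = "exact",
                  base_score = 0, seed = seed),
    data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
    nrounds = nrounds, verbose = 0)
  list(booster = booster, x = x)
}

# wrap a bare booster as a tv_model so the shap module can drive it
as_tv_model <- function(booster, feature_names) {
  structure(list(booster = booster, encoding = NULL,
                 config = NULL, feature_names = feature_names,
                 train_idx = NULL),
            class = "tv_model")
}
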