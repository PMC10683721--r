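# Greedy forward feature selection scored by out-of-fold ROC AUC, plus the
# pairwise feature r-squared matrix.

#' Greedy forward feature selection by out-of-fold ROC AUC
#'
#' At each round every remaining candidate is added in turn to the selected
#' set, a k-fold model is fitted, and the candidate with the best AUC is
#' kept (ties broken lexicographically). Selection stops when the AUC is
#' within `epsilon` of the all-candidates model, when `max_features` is
#' reached, or when candidates are exhausted. `stroke_team` counts as a
#' single candidate (its whole indicator block enters together).
#'
#' @param table Labelled patient table.
#' @param candidates Character vector of feature names to select among;
#'   defaults to all features in the table.
#' @param k_folds Cross-validation folds used for scoring.
#' @param epsilon Stop once the selected-set AUC is within this much of the
#'   full-candidate-set AUC; `NULL` disables the stop rule so selection runs
#'   to `max_features` (useful when the full selection order is wanted).
#' @param max_features Optional cap on the number of selected features.
#' @param config A [model_config()] for the scoring fits.
#' @param pool_folds Score by pooled out-of-fold predictions (`TRUE`) or by
#'   the mean of per-fold AUCs (`FALSE`, default).
#' @return Object of class `selection_trace`: data.frame with one row per
#'   round (`round`, `feature`, `auc`), plus attributes `full_auc` and
#'   `stopped_early`.
#' @export
forward_select <- function(table, candidates = NULL, k_folds = 5,
                           epsilon = 0.001, max_features = NULL,
                           config = model_config("kfold", n_folds = k_folds),
                           pool_folds = FALSE) {
  if (is.null(candidates)) {
    candidates <- setdiff(names(table), "thrombolysis")
  }
  if (length(candidates) == 0) stop("empty candidate list")
  if (!is.null(epsilon) && epsilon < 0) stop("`epsilon` must be >= 0")
  enc <- encode_features(table)
  y <- enc$label
  fold <- stratified_folds(y, k_folds, config$seed)

  cols_for <- function(feats) {
    unlist(lapply(feats, function(f) {
      if (f == "stroke_team") paste0("team::", enc$encoding$teams) else f
    }))
  }
  score <- function(feats) {
    x <- enc$x[, cols_for(feats), drop = FALSE]
    oof <- numeric(length(y))
    aucs <- numeric(k_folds)
    for (k in seq_len(k_folds)) {
      tr <- fold != k
      booster <- fit_booster(x[tr, , drop = FALSE], y[tr], config)
      oof[!tr] <- stats::predict(booster, x[!tr, , drop = FALSE])
      aucs[k] <- fast_auc(oof[!tr], y[!tr])
    }
    if (pool_folds) fast_auc(oof, y) else mean(aucs)
  }

  full_auc <- score(candidates)
  selected <- character(0)
  trace <- data.frame(round = integer(0), feature = character(0),
                      auc = numeric(0), stringsAsFactors = FALSE)
  remaining <- sort(candidates)
  stopped_early <- FALSE
  cap <- if (is.null(max_features)) length(candidates) else max_features
  while (length(remaining) > 0 && length(selected) < cap) {
    aucs <- vapply(remaining, function(f) score(c(selected, f)), 0)
    best <- remaining[which.max(aucs)]  # first max = lexicographic tie-break
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
    trace <- rbind(trace, data.frame(round = length(selected), feature = best,
                                     auc = max(aucs), stringsAsFactors = FALSE))
    if (!is.null(epsilon) && max(aucs) >= full_auc - epsilon) {
      stopped_early <- TRUE
      break
    }
  }
  structure(trace, full_auc = full_auc, stopped_early = stopped_early,
            class = c("selection_trace", "data.frame"))
}

#' Pairwise r-squared between features
#'
#' Squared Pearson correlation between each pair of features; binary
#' features enter as 0/1 numerics. Constant features get r-squared 0 with a
#' warning. `stroke_team` (categorical) is excluded by the default feature
#' choice.
#'
#' @param table Patient table.
#' @param features Features to correlate; defaults to the nine numeric model
#'   features.
#' @return Symmetric matrix of r-squared values with unit diagonal.
#' @export
pairwise_feature_r2 <- function(table,
                                features = setdiff(patient_schema_columns(),
                                                   "stroke_team")) {
  if (length(features) < 2) stop("need at least two features")
  x <- as.matrix(table[, features, drop = FALSE])
  storage.mode(x) <- "double"
  const <- apply(x, 2, stats::sd) == 0
  if (any(const)) {
    warning("constant feature(s) recorded as r2 = 0: ",
            paste(features[const], collapse = ", "))
  }
  r2 <- matrix(0, length(features), length(features),
               dimnames = list(features, features))
  ok <- !const
  if (any(ok)) r2[ok, ok] <- stats::cor(x[, ok, drop = FALSE])^2
  diag(r2) <- 1
  r2
}
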