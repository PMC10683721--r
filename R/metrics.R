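# Accuracy surface of the classifier: overall accuracy, ROC AUC, the
# equal-sensitivity/specificity point, and hospital-level agreement between
# predicted and observed thrombolysis rates.

# Rank-statistic ROC AUC (Mann-Whitney); cross-checked against pROC in the
# test suite. Fast enough to sit inside the forward-selection loop.
fast_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: single-class input")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Threshold where sensitivity equals specificity
#'
#' Sweeps thresholds over the score range and linearly interpolates between
#' adjacent thresholds to find the crossing of the sensitivity and
#' specificity curves.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels.
#' @return List with `threshold` and `value` (the common
#'   sensitivity = specificity level, in `[0, 1]`).
#' @export
equal_sens_spec_point <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2) {
    stop("equal_sens_spec_point requires both classes")
  }
  th <- sort(unique(scores))
  # predict positive when score >= threshold
  sens <- vapply(th, function(t) mean(scores[labels == 1] >= t), 0)
  spec <- vapply(th, function(t) mean(scores[labels == 0] < t), 0)
  d <- sens - spec  # decreasing from +1 towards -1
  if (all(d >= 0)) {
    k <- length(th)
    return(list(threshold = th[k], value = (sens[k] + spec[k]) / 2))
  }
  k <- which(d < 0)[1]
  if (k == 1) return(list(threshold = th[1], value = (sens[1] + spec[1]) / 2))
  w <- d[k - 1] / (d[k - 1] - d[k])
  list(threshold = th[k - 1] + w * (th[k] - th[k - 1]),
       value = sens[k - 1] + w * (sens[k] - sens[k - 1]))
}

#' Hospital-level agreement between predicted and observed thrombolysis use
#'
#' Per-hospital predicted rate is the mean predicted probability of its
#' patients; observed rate is the label mean. Agreement is the squared
#' Pearson correlation and the mean absolute error in percentage points.
#'
#' @param probs Per-row predicted probabilities.
#' @param table The patient table the probabilities refer to.
#' @return List with `r2`, `mae_points` and the per-hospital `rates`
#'   data.frame (`stroke_team`, `n`, `observed`, `predicted`, as
#'   proportions).
#' @export
hospital_level_agreement <- function(probs, table) {
  stopifnot(length(probs) == nrow(table))
  team <- as.character(table$stroke_team)
  keep <- table(team)
  if (any(keep == 0)) warning("hospitals with zero rows excluded")
  obs <- tapply(table$thrombolysis, team, mean)
  pred <- tapply(probs, team, mean)
  rates <- data.frame(stroke_team = names(obs), n = as.integer(keep[names(obs)]),
                      observed = as.numeric(obs), predicted = as.numeric(pred),
                      stringsAsFactors = FALSE)
  r2 <- if (stats::sd(rates$predicted) == 0 || stats::sd(rates$observed) == 0) NA_real_
        else stats::cor(rates$observed, rates$predicted)^2
  list(r2 = r2,
       mae_points = mean(abs(rates$observed - rates$predicted)) * 100,
       rates = rates)
}

#' Accuracy surface from predictions and labels
#'
#' @param probs Predicted probabilities (out-of-fold for the k-fold model).
#' @param labels Binary labels.
#' @param table Optional patient table for the hospital-level agreement.
#' @param threshold Probability threshold for overall accuracy.
#' @return Object of class `metrics_report`: accuracy, ROC AUC, the
#'   equal-sensitivity/specificity point, and (when `table` is given)
#'   hospital-level r-squared and MAE.
#' @export
metrics_report <- function(probs, labels, table = NULL, threshold = 0.5) {
  bal <- equal_sens_spec_point(probs, labels)
  out <- list(
    accuracy = mean((probs >= threshold) == (labels == 1)),
    roc_auc = fast_auc(probs, labels),
    balanced_value = bal$value,
    balanced_threshold = bal$threshold
  )
  if (!is.null(table)) {
    agr <- hospital_level_agreement(probs, table)
    out$hospital_r2 <- agr$r2
    out$hospital_mae_points <- agr$mae_points
    out$hospital_rates <- agr$rates
  }
  class(out) <- "metrics_report"
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.3f | ROC AUC %.3f | sens=spec %.3f @ %.3f\n",
              x$accuracy, x$roc_auc, x$balanced_value, x$balanced_threshold))
  if (!is.null(x$hospital_r2)) {
    cat(sprintf("hospital-level r2 %.3f | MAE %.2f percentage points\n",
                x$hospital_r2, x$hospital_mae_points))
  }
  invisible(x)
}
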