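# SHAP decomposition of the fitted classifier in log-odds: per-patient
# values, main effects and pairwise interactions, the subset SHAP
# statistic, waterfalls and binned feature-effect summaries. The fast path
# is path-dependent TreeSHAP (training data as background); the hospital
# one-hot block is aggregated into a single "stroke_team" pseudo-feature
# for all reporting.

# reporting-feature grouping of encoded columns
encoded_groups <- function(feature_names) {
  rep_name <- ifelse(grepl("^team::", feature_names), "stroke_team",
                     feature_names)
  split(seq_along(feature_names), factor(rep_name, unique(rep_name)))
}

#' Per-patient SHAP values in log-odds
#'
#' Computes TreeSHAP contributions for every row and aggregates the
#' hospital indicator block into one `stroke_team` contribution. The
#' additivity contract `base + sum(values) == raw margin` holds for every
#' row.
#'
#' @param model A fitted `tv_model`.
#' @param table Patient table (or pre-encoded matrix).
#' @return Object of class `shap_matrix`: list with `values` (rows x
#'   reporting features), `base` (per-row expected margin), `margin`
#'   (per-row raw model margin) and `features`.
#' @export
compute_shap <- function(model, table) {
  x <- if (is.matrix(table)) table else
    encode_features(table, model$encoding)$x
  x <- x[, model$feature_names, drop = FALSE]
  ctr <- stats::predict(model$booster, x, predcontrib = TRUE)
  m <- ncol(ctr) - 1L  # last column is the bias term
  groups <- encoded_groups(colnames(ctr)[seq_len(m)])
  values <- vapply(groups,
                   function(ix) rowSums(ctr[, ix, drop = FALSE]),
                   numeric(nrow(ctr)))
  if (nrow(ctr) == 1) values <- matrix(values, 1, dimnames = list(NULL, names(groups)))
  structure(list(values = values, base = ctr[, m + 1L],
                 margin = stats::predict(model$booster, x, outputmargin = TRUE),
                 features = names(groups)),
            class = "shap_matrix")
}

#' @export
print.shap_matrix <- function(x, ...) {
  cat("<shap_matrix>", nrow(x$values), "patients x", ncol(x$values),
      "features (log-odds)\n")
  invisible(x)
}

#' Per-patient SHAP interaction tensor
#'
#' Symmetric per-patient feature-by-feature matrices in log-odds: the
#' diagonal holds main effects, off-diagonal `(i, j)` holds half the
#' pairwise interaction between `i` and `j` (so that the row sum over `j`
#' recovers feature `i`'s total SHAP value). The hospital one-hot block is
#' aggregated on both axes.
#'
#' @inheritParams compute_shap
#' @return Object of class `shap_tensor`: list with `values` (array rows x
#'   features x features), `base`, `margin` and `features`.
#' @export
compute_interactions <- function(model, table) {
  x <- if (is.matrix(table)) table else
    encode_features(table, model$encoding)$x
  x <- x[, model$feature_names, drop = FALSE]
  inter <- stats::predict(model$booster, x, predinteraction = TRUE)
  m <- dim(inter)[2] - 1L
  n <- dim(inter)[1]
  base <- inter[, m + 1L, m + 1L]
  inter <- inter[, seq_len(m), seq_len(m), drop = FALSE]
  groups <- encoded_groups(colnames(x))
  k <- length(groups)
  agg <- matrix(0, m, k, dimnames = list(NULL, names(groups)))
  for (j in seq_len(k)) agg[groups[[j]], j] <- 1
  # contract both feature axes with the aggregation matrix
  t1 <- matrix(aperm(inter, c(1, 3, 2)), n * m, m) %*% agg    # sum over axis 2
  t1 <- aperm(array(t1, c(n, m, k)), c(1, 3, 2))              # n x k x m
  t2 <- matrix(t1, n * k, m) %*% agg                          # sum over axis 3
  values <- array(t2, c(n, k, k),
                  dimnames = list(NULL, names(groups), names(groups)))
  structure(list(values = values, base = base,
                 margin = stats::predict(model$booster, x, outputmargin = TRUE),
                 features = names(groups)),
            class = "shap_tensor")
}

#' @export
print.shap_tensor <- function(x, ...) {
  cat("<shap_tensor>", dim(x$values)[1], "patients x", dim(x$values)[2],
      "x", dim(x$values)[3], "features (log-odds)\n")
  invisible(x)
}

#' Total SHAP values recovered from an interaction tensor
#'
#' Row sums of the symmetric interaction matrices: main effect plus all
#' halved pairwise interactions, per feature per patient.
#'
#' @param tensor A `shap_tensor`.
#' @return Matrix rows x features.
#' @export
tensor_row_sums <- function(tensor) {
  apply(tensor$values, c(1, 2), sum)
}

#' Subset SHAP values under a feature partition
#'
#' The subset SHAP value of feature `i` is its main effect plus its
#' interaction effects with the other features in the same subset only;
#' cross-subset interaction terms are excluded. Under the halved symmetric
#' storage of the interaction tensor this is the row sum restricted to
#' same-subset columns, so a partition with a single subset recovers each
#' feature's total SHAP value exactly, and a partition into singletons
#' recovers the main effects.
#'
#' @param tensor A `shap_tensor`.
#' @param partition Named list of character vectors partitioning the
#'   tensor's features into disjoint, exhaustive subsets.
#' @return Object of class `subset_attribution`: list with `values` (rows x
#'   features), `subset_of` (feature to subset-name map) and `partition`.
#' @export
subset_shap <- function(tensor, partition) {
  feats <- tensor$features
  all_assigned <- unlist(partition, use.names = FALSE)
  if (anyDuplicated(all_assigned)) {
    stop("partition subsets must be disjoint")
  }
  missing <- setdiff(feats, all_assigned)
  if (length(missing)) {
    stop("feature(s) missing from partition: ", paste(missing, collapse = ", "))
  }
  subset_of <- stats::setNames(
    rep(names(partition), lengths(partition)), all_assigned)[feats]
  n <- dim(tensor$values)[1]
  values <- matrix(0, n, length(feats), dimnames = list(NULL, feats))
  for (i in seq_along(feats)) {
    same <- which(subset_of == subset_of[i])
    values[, i] <- rowSums(tensor$values[, i, same, drop = FALSE], dims = 1)
  }
  structure(list(values = values, subset_of = subset_of,
                 partition = partition),
            class = "subset_attribution")
}

#' Waterfall decomposition of one patient's prediction
#'
#' Orders the patient's SHAP contributions by absolute size and walks the
#' cumulative log-odds from the base value to the final prediction,
#' reporting each partial sum on the probability scale.
#'
#' @param shap_row Named numeric vector of one patient's SHAP values.
#' @param base_value The model's base (expected) log-odds.
#' @return Data.frame with one row per feature: `feature`, `contribution`
#'   (log-odds), `cumulative_log_odds`, `cumulative_probability`. The final
#'   `cumulative_probability` equals the model's predicted probability.
#' @export
waterfall <- function(shap_row, base_value) {
  ord <- order(abs(shap_row), decreasing = TRUE)
  cum <- base_value + cumsum(shap_row[ord])
  data.frame(feature = names(shap_row)[ord],
             contribution = as.numeric(shap_row[ord]),
             cumulative_log_odds = as.numeric(cum),
             cumulative_probability = as.numeric(stats::plogis(cum)),
             stringsAsFactors = FALSE)
}

#' Binned summary of SHAP values against feature values
#'
#' Medians and quartiles of a feature's SHAP values within bins of the
#' feature's own values — the tabular counterpart of a violin plot of SHAP
#' against feature value. Empty bins are omitted with a warning.
#'
#' @param table Patient table aligned to the SHAP matrix.
#' @param shap A `shap_matrix`.
#' @param feature Feature name.
#' @param bins Numeric break points for a continuous feature; `NULL` (the
#'   default) groups by distinct value, which suits binary and small
#'   integer features.
#' @return Data.frame with `bin`, `n`, `median`, `q25`, `q75`.
#' @export
shap_vs_value_summary <- function(table, shap, feature, bins = NULL) {
  stopifnot(feature %in% colnames(shap$values))
  v <- table[[feature]]
  s <- shap$values[, feature]
  grp <- if (is.null(bins)) factor(v) else
    cut(v, breaks = bins, right = FALSE, include.lowest = TRUE)
  empty <- setdiff(levels(grp), unique(as.character(grp[!is.na(grp)])))
  if (length(empty)) warning("empty bin(s) omitted: ", paste(empty, collapse = ", "))
  keep <- !is.na(grp)
  med <- tapply(s[keep], droplevels(grp[keep]), stats::median)
  q25 <- tapply(s[keep], droplevels(grp[keep]), stats::quantile, 0.25)
  q75 <- tapply(s[keep], droplevels(grp[keep]), stats::quantile, 0.75)
  n <- tapply(s[keep], droplevels(grp[keep]), length)
  data.frame(bin = names(med), n = as.integer(n), median = as.numeric(med),
             q25 = as.numeric(q25), q75 = as.numeric(q75),
             stringsAsFactors = FALSE)
}

#' Fold change in the odds of thrombolysis between two feature bins
#'
#' `exp(median SHAP in bin a - median SHAP in bin b)`: how many times the
#' odds of receiving thrombolysis change between the two bins.
#'
#' @param summary Output of [shap_vs_value_summary()].
#' @param bin_a,bin_b Bin labels as they appear in `summary$bin`.
#' @return Positive scalar fold change.
#' @export
fold_change <- function(summary, bin_a, bin_b) {
  ma <- summary$median[match(bin_a, summary$bin)]
  mb <- summary$median[match(bin_b, summary$bin)]
  if (is.na(ma) || is.na(mb)) stop("bin not found in summary")
  exp(ma - mb)
}

#' Fold change in the odds across a feature-value span
#'
#' Estimates the change in log-odds between two feature values by ordinary
#' least squares of the binned median SHAP values on the within-bin median
#' feature values, then reports `exp(fit(from) - fit(to))`. For a feature
#' whose effect declines over the span this is the fold reduction in the
#' odds of thrombolysis, and it is robust to sparsely populated extreme
#' bins where a single bin's median is noisy.
#'
#' @param table Patient table aligned to the SHAP matrix.
#' @param shap A `shap_matrix`.
#' @param feature Feature name.
#' @param from,to Feature values delimiting the span.
#' @param bins Break points over the span (default 8 equal bins).
#' @return Positive scalar fold change.
#' @export
fold_change_span <- function(table, shap, feature, from, to,
                             bins = seq(from, to, length.out = 9)) {
  v <- table[[feature]]
  s <- shap$values[, feature]
  grp <- cut(v, breaks = bins, right = FALSE, include.lowest = TRUE)
  keep <- !is.na(grp)
  med_s <- tapply(s[keep], droplevels(grp[keep]), stats::median)
  med_v <- tapply(v[keep], droplevels(grp[keep]), stats::median)
  if (length(med_s) < 2) stop("need at least two populated bins")
  fit <- stats::lm(med_s ~ med_v)
  slope <- unname(stats::coef(fit)[2])
  exp(slope * (from - to))
}
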