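# Partition of between-hospital variance in observed thrombolysis rates
# into patient-descriptive and hospital-descriptive subset SHAP components.

#' Default patient/hospital feature partition
#'
#' Eight patient-descriptive features (the patient's characteristics) and
#' two hospital-descriptive features: arrival-to-scan time (an in-hospital
#' process) and the hospital attended. The assignment of arrival-to-scan
#' time is configurable because scan priority may partly reflect clinical
#' presentation.
#'
#' @return Named list with `patient` and `hospital` character vectors.
#' @export
default_subset_assignment <- function() {
  list(
    patient = c("age", "nihss", "prior_mrs", "onset_to_arrival",
                "infarction", "precise_onset", "anticoagulant",
                "onset_during_sleep"),
    hospital = c("arrival_to_scan", "stroke_team")
  )
}

#' Per-hospital means of subset SHAP sums
#'
#' For each hospital, the mean over its patients of the summed subset SHAP
#' values within each subset, plus the hospital's observed thrombolysis
#' rate (in percent). Hospitals with no patients are excluded with a
#' warning.
#'
#' @param attribution A `subset_attribution` aligned to `table`.
#' @param table The labelled patient table.
#' @return Data.frame with `stroke_team`, `n`, one `mean_<subset>` column
#'   per subset, and `observed_pct`.
#' @export
per_hospital_subset_means <- function(attribution, table) {
  if (nrow(attribution$values) != nrow(table)) {
    stop("attribution is not aligned to the table")
  }
  team <- as.character(table$stroke_team)
  subsets <- names(attribution$partition)
  out <- data.frame(stroke_team = sort(unique(team)), stringsAsFactors = FALSE)
  out$n <- as.integer(table(team)[out$stroke_team])
  if (any(out$n == 0)) {
    warning("hospitals with zero rows excluded")
    out <- out[out$n > 0, , drop = FALSE]
  }
  for (s in subsets) {
    feats <- intersect(colnames(attribution$values),
                       attribution$partition[[s]])
    sums <- rowSums(attribution$values[, feats, drop = FALSE])
    out[[paste0("mean_", s)]] <-
      as.numeric(tapply(sums, team, mean)[out$stroke_team])
  }
  out$observed_pct <- 100 * as.numeric(
    tapply(table$thrombolysis, team, mean)[out$stroke_team])
  out
}

#' Regression partition of between-hospital variance
#'
#' Ordinary least squares of the observed per-hospital thrombolysis rate
#' (percent) on (a) the mean patient-subset SHAP sum, (b) the mean
#' hospital-subset SHAP sum, and (c) both together, reporting each fit's
#' r-squared and overall-F p-value. The combined fit nests the single
#' fits, so its r-squared is at least the larger of the two.
#'
#' @param subset_means Output of [per_hospital_subset_means()] with
#'   `mean_patient` and `mean_hospital` columns.
#' @return Object of class `partition_report`: list with `r2` and `p`
#'   (named vectors over patient / hospital / combined), and `fits` (the lm
#'   objects).
#' @export
regress_partition <- function(subset_means) {
  if (nrow(subset_means) < 3) stop("need at least 3 hospitals")
  need <- c("mean_patient", "mean_hospital", "observed_pct")
  if (!all(need %in% names(subset_means))) {
    stop("subset_means must carry ", paste(need, collapse = ", "))
  }
  fits <- list(
    patient = stats::lm(observed_pct ~ mean_patient, data = subset_means),
    hospital = stats::lm(observed_pct ~ mean_hospital, data = subset_means),
    combined = stats::lm(observed_pct ~ mean_patient + mean_hospital,
                         data = subset_means)
  )
  if (any(vapply(fits, function(f) anyNA(stats::coef(f)), TRUE))) {
    stop("rank-deficient design in variance-partition regression")
  }
  overall_p <- function(f) {
    fs <- summary(f)$fstatistic
    unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE))
  }
  structure(
    list(r2 = vapply(fits, function(f) summary(f)$r.squared, 0),
         p = vapply(fits, overall_p, 0),
         fits = fits),
    class = "partition_report")
}

#' @export
print.partition_report <- function(x, ...) {
  cat("between-hospital variance explained (r-squared):\n")
  for (nm in names(x$r2)) {
    cat(sprintf("  %-9s %.3f (p = %.2g)\n", nm, x$r2[nm], x$p[nm]))
  }
  invisible(x)
}

#' Out-of-fold predictive gain of the hospital-identity feature
#'
#' Pooled out-of-fold ROC AUC of a k-fold model with all features minus the
#' AUC of the same model trained blind to `stroke_team`. Used to decide
#' whether hospital identity carries real predictive signal before it is
#' given attribution in the variance partition.
#'
#' @param table Labelled patient table.
#' @param config A [model_config()] for the scoring fits.
#' @return Scalar AUC gain.
#' @export
hospital_identity_gain <- function(table,
                                   config = model_config("kfold",
                                                         n_folds = 3)) {
  feats <- setdiff(names(table), "thrombolysis")
  with_team <- fit_kfold(table, config)$metrics$roc_auc
  without_team <- fit_kfold(table, config,
                            features = setdiff(feats, "stroke_team"))
  with_team - without_team$metrics$roc_auc
}

#' Full variance-partition analysis of a patient table
#'
#' Runs the whole chain: decide by out-of-fold AUC whether hospital
#' identity is informative (an uninformative one-hot hospital block would
#' otherwise soak up per-hospital label noise in-sample and masquerade as
#' "explained" between-hospital variance), fit the all-data model with or
#' without `stroke_team` accordingly, decompose predictions into subset
#' SHAP values, average them per hospital and regress the observed rates.
#'
#' @param table Labelled patient table (the ten model features only).
#' @param config A [model_config()] for the all-data fit.
#' @param assignment Feature partition, see [default_subset_assignment()].
#' @param gate_epsilon Minimum out-of-fold AUC gain for hospital identity
#'   to enter the model (the same equivalence threshold used in feature
#'   selection).
#' @return List with `report` (a `partition_report`), `means` (per-hospital
#'   subset means), `used_hospital_identity` and `gain`.
#' @export
variance_partition_analysis <- function(table,
                                        config = model_config("all_data"),
                                        assignment = default_subset_assignment(),
                                        gate_epsilon = 0.001) {
  gain <- hospital_identity_gain(table, model_config(
    "kfold", n_folds = 3, nrounds = config$nrounds,
    max_depth = config$max_depth, eta = config$eta, seed = config$seed))
  use_team <- gain >= gate_epsilon
  feats <- setdiff(names(table), "thrombolysis")
  fit <- fit_all_data(table, config,
                      features = if (use_team) NULL else
                        setdiff(feats, "stroke_team"))
  tensor <- compute_interactions(fit, table)
  asg <- lapply(assignment, intersect, tensor$features)
  uncovered <- setdiff(tensor$features, unlist(asg))
  if (length(uncovered)) {
    stop("features not covered by the subset assignment: ",
         paste(uncovered, collapse = ", "))
  }
  attribution <- subset_shap(tensor, asg[lengths(asg) > 0])
  means <- per_hospital_subset_means(attribution, table)
  list(report = regress_partition(means), means = means,
       used_hospital_identity = use_team, gain = gain)
}
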