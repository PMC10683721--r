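# Hospital propensity to thrombolyse: mean SHAP main effect of the
# hospital-attended pseudo-feature, counterfactual identical-cohort
# predictions, and correlations with hospital process descriptors.

#' Mean hospital SHAP main effect per hospital
#'
#' Groups patients by attended hospital and averages the main effect
#' (diagonal term) of the aggregated `stroke_team` pseudo-feature, together
#' with the observed thrombolysis rate. A model trained without the
#' hospital feature yields main effects of zero for every hospital.
#'
#' @param tensor A `shap_tensor` aligned row-for-row to `table`.
#' @param table The labelled patient table the tensor was computed on.
#' @param hospitals Optional hospital profile table
#'   ([sample_hospitals()]-like) merged onto the result by `stroke_team`.
#' @return Data.frame of class `hospital_effect_table`: one row per
#'   hospital with `stroke_team`, `n`, `mean_main_effect` (log-odds),
#'   `observed_rate`, plus any merged descriptor columns.
#' @export
mean_hospital_main_effect <- function(tensor, table, hospitals = NULL) {
  if (dim(tensor$values)[1] != nrow(table)) {
    stop("tensor is not aligned to the table")
  }
  team <- as.character(table$stroke_team)
  main <- if ("stroke_team" %in% tensor$features) {
    tensor$values[, "stroke_team", "stroke_team"]
  } else {
    rep(0, nrow(table))
  }
  out <- data.frame(
    stroke_team = sort(unique(team)),
    stringsAsFactors = FALSE
  )
  out$n <- as.integer(table(team)[out$stroke_team])
  out$mean_main_effect <- as.numeric(tapply(main, team, mean)[out$stroke_team])
  out$observed_rate <- as.numeric(
    tapply(table$thrombolysis, team, mean)[out$stroke_team])
  if (!is.null(hospitals)) {
    out <- merge(out, hospitals, by = "stroke_team", sort = TRUE)
  }
  class(out) <- c("hospital_effect_table", "data.frame")
  out
}

#' Counterfactual identical-cohort predictions at every hospital
#'
#' Rewrites the held-out cohort's hospital indicator block to each hospital
#' in turn, predicts thrombolysis probabilities with the holdout model, and
#' records the mean predicted rate per hospital — isolating hospital
#' behaviour from case mix, since every hospital sees the identical
#' patients. Optionally also records the mean hospital SHAP main effect on
#' (a fixed subset of) the counterfactual rows.
#'
#' @param model The holdout `tv_model` (trained without the cohort).
#' @param cohort Held-out patient table (original, un-encoded features).
#' @param cohort_idx Optional row indices of the cohort in the model's
#'   training table; used to verify the cohort is disjoint from training.
#' @param teams Teams to cycle through; defaults to the model's encoding.
#' @param main_effect_rows Number of leading cohort rows on which the
#'   per-hospital SHAP main effect is computed (interaction tensors are
#'   expensive; the same rows are used at every hospital so the means stay
#'   comparable). Set to 0 to skip.
#' @return Data.frame of class `counterfactual_result`: per hospital
#'   `stroke_team`, `predicted_rate` and (when requested)
#'   `mean_main_effect`.
#' @export
counterfactual_cohort <- function(model, cohort, cohort_idx = NULL,
                                  teams = NULL, main_effect_rows = 250) {
  if (!is.null(cohort_idx) && length(intersect(cohort_idx, model$train_idx))) {
    stop("leakage error: cohort overlaps the model's training rows")
  }
  if (is.null(teams)) teams <- model$encoding$teams
  enc <- encode_features(cohort, model$encoding)
  x <- enc$x[, model$feature_names, drop = FALSE]
  has_team <- any(grepl("^team::", model$feature_names))
  me_rows <- min(main_effect_rows, nrow(cohort))
  rate <- numeric(length(teams))
  main <- rep(NA_real_, length(teams))
  for (h in seq_along(teams)) {
    xh <- if (has_team) {
      set_team(enc$x, teams[h], model$encoding)[, model$feature_names,
                                                drop = FALSE]
    } else {
      x
    }
    rate[h] <- mean(stats::predict(model$booster, xh))
    if (me_rows > 0 && has_team) {
      tens <- compute_interactions(model, xh[seq_len(me_rows), , drop = FALSE])
      main[h] <- mean(tens$values[, "stroke_team", "stroke_team"])
    }
  }
  if (me_rows > 0 && !has_team) main <- rep(0, length(teams))
  out <- data.frame(stroke_team = teams, predicted_rate = rate,
                    mean_main_effect = main, stringsAsFactors = FALSE)
  if (me_rows == 0) out$mean_main_effect <- NULL
  class(out) <- c("counterfactual_result", "data.frame")
  out
}

#' Correlation of hospital process descriptors with hospital SHAP effects
#'
#' Ordinary least squares of the mean hospital SHAP main effect on each
#' process descriptor (admission numbers, scan-to-needle speed, ...), with
#' the squared Pearson correlation and the two-sided p-value of the slope.
#' Constant descriptors are skipped with a warning.
#'
#' @param effects A `hospital_effect_table` carrying descriptor columns.
#' @param descriptors Descriptor column names; defaults to the generator's
#'   process descriptors that are present.
#' @return Data.frame with `descriptor`, `slope`, `r2`, `p`.
#' @export
process_correlates <- function(effects,
                               descriptors = intersect(
                                 c("admissions_per_year",
                                   "median_scan_to_needle_min",
                                   "arrival_to_scan_location"),
                                 names(effects))) {
  rows <- lapply(descriptors, function(d) {
    v <- effects[[d]]
    if (is.null(v)) stop("descriptor `", d, "` not present")
    if (stats::sd(v) == 0) {
      warning("constant descriptor skipped: ", d)
      return(NULL)
    }
    fit <- stats::lm(effects$mean_main_effect ~ v)
    sm <- summary(fit)
    data.frame(descriptor = d, slope = unname(stats::coef(fit)[2]),
               r2 = sm$r.squared,
               p = unname(sm$coefficients[2, 4]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}
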