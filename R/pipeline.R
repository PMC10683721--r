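# End-to-end orchestration: generate -> train -> select features -> explain
# -> hospital analysis -> variance partition -> subgroups, with one config,
# reproducible seeding and a checksummed run manifest.

#' Configuration of a full pipeline run
#'
#' @param seed Master seed; the generator, the model fits and the holdout
#'   draw all derive their seeds from it.
#' @param generator A [generator_config()] (its own seed is overridden by
#'   the master seed).
#' @param model A [model_config()] template for the fits.
#' @param holdout_size Held-out cohort size for the counterfactual stage.
#' @param selection Run the (expensive) forward-selection stage.
#' @param selection_folds,selection_epsilon Forward-selection settings.
#' @param subset_assignment Feature partition for the variance stage.
#' @param subgroups Subgroup definitions for the subgroup stage.
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 42,
                       generator = generator_config(),
                       model = model_config("all_data"),
                       holdout_size = 2000,
                       selection = FALSE,
                       selection_folds = 3,
                       selection_epsilon = 0.001,
                       subset_assignment = default_subset_assignment(),
                       subgroups = builtin_subgroups()) {
  generator$seed <- as.integer(seed)
  model$seed <- as.integer(seed)
  cfg <- list(seed = as.integer(seed), generator = generator, model = model,
              holdout_size = as.integer(holdout_size),
              selection = isTRUE(selection),
              selection_folds = as.integer(selection_folds),
              selection_epsilon = selection_epsilon,
              subset_assignment = subset_assignment, subgroups = subgroups)
  class(cfg) <- "run_config"
  cfg
}

pipeline_stages <- function() {
  c("generate", "train", "select_features", "explain", "hospital_analysis",
    "variance", "subgroups")
}

write_stage_csv <- function(df, out_dir, name) {
  path <- file.path(out_dir, paste0(name, ".csv"))
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the whole analysis pipeline
#'
#' Executes every stage in order on a freshly generated synthetic dataset,
#' writes each stage's outputs as CSV/JSON under `out_dir`, and returns a
#' manifest recording stage outputs, seeds and file checksums. Re-running
#' with the same config reproduces identical outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return The run manifest (list), invisibly written to
#'   `manifest.json` as well.
#' @export
run_all <- function(config = run_config(), out_dir = tempfile("tvrun")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # generate
  ds <- stage("generate", {
    d <- generate_dataset(config$generator)
    write_dataset(d$patients, file.path(out_dir, "patients.csv"),
                  truth = list(hospitals = d$hospitals,
                               intercept = d$config$intercept,
                               effect_params = d$config$effect_params,
                               seed = d$config$seed))
    d
  })
  files <- c(files, file.path(out_dir, c("patients.csv",
                                         "patients.csv.truth.json")))

  # train
  trained <- stage("train", {
    if (config$holdout_size >= nrow(ds$patients)) {
      stop("config error: holdout larger than the dataset")
    }
    kcfg <- config$model; kcfg$variant <- "kfold"
    kf <- fit_kfold(ds$patients, kcfg)
    acfg <- config$model; acfg$variant <- "all_data"
    all_fit <- fit_all_data(ds$patients, acfg)
    hcfg <- config$model
    hcfg$variant <- "holdout"; hcfg$holdout_size <- config$holdout_size
    hold <- fit_holdout(ds$patients, hcfg)
    metrics <- kf$metrics
    jsonlite::write_json(
      list(accuracy = metrics$accuracy, roc_auc = metrics$roc_auc,
           balanced_value = metrics$balanced_value,
           hospital_r2 = metrics$hospital_r2,
           hospital_mae_points = metrics$hospital_mae_points),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
    list(kfold = kf, all_data = all_fit, holdout = hold)
  })
  files <- c(files, file.path(out_dir, "metrics.json"))

  # select features
  if (config$selection) {
    sel <- stage("select_features", {
      forward_select(ds$patients, k_folds = config$selection_folds,
                     epsilon = config$selection_epsilon,
                     config = config$model)
    })
    files <- c(files, write_stage_csv(as.data.frame(sel), out_dir,
                                      "selection_trace"))
  }

  # explain
  expl <- stage("explain", {
    shap <- compute_shap(trained$all_data, ds$patients)
    tensor <- compute_interactions(trained$all_data, ds$patients)
    fc <- lapply(stats::setNames(nm = shap$features), function(f) {
      s <- shap_vs_value_summary(ds$patients, shap, f,
                                 bins = feature_summary_bins(f))
      s$feature <- f
      s
    })
    files <- c(files, write_stage_csv(do.call(rbind, fc), out_dir,
                                       "shap_by_feature_value"))
    list(shap = shap, tensor = tensor)
  })

  # hospital analysis
  hosp <- stage("hospital_analysis", {
    eff <- mean_hospital_main_effect(expl$tensor, ds$patients, ds$hospitals)
    cf <- counterfactual_cohort(trained$holdout$model, trained$holdout$cohort,
                                cohort_idx = trained$holdout$holdout_idx)
    pc <- process_correlates(eff)
    files <- c(files,
                write_stage_csv(as.data.frame(eff), out_dir,
                                "hospital_effects"),
                write_stage_csv(as.data.frame(cf), out_dir,
                                "counterfactual_rates"),
                write_stage_csv(pc, out_dir, "process_correlates"))
    list(effects = eff, counterfactual = cf, process = pc)
  })

  # variance partition (hospital identity enters only when it carries
  # out-of-fold signal; the full-feature tensor is reused when it does)
  vp <- stage("variance", {
    gain <- hospital_identity_gain(ds$patients, model_config(
      "kfold", n_folds = 3, nrounds = config$model$nrounds,
      max_depth = config$model$max_depth, eta = config$model$eta,
      seed = config$seed))
    if (gain >= config$selection_epsilon) {
      tensor <- expl$tensor
    } else {
      feats <- setdiff(names(ds$patients), c("thrombolysis", "stroke_team"))
      blind <- fit_all_data(ds$patients, config$model, features = feats)
      tensor <- compute_interactions(blind, ds$patients)
    }
    asg <- lapply(config$subset_assignment, intersect, tensor$features)
    # decoy features, if any, count as patient-descriptive
    asg$patient <- c(asg$patient, setdiff(tensor$features, unlist(asg)))
    attribution <- subset_shap(tensor, asg[lengths(asg) > 0])
    means <- per_hospital_subset_means(attribution, ds$patients)
    rep <- regress_partition(means)
    files <- c(files, write_stage_csv(means, out_dir,
                                       "hospital_subset_means"))
    jsonlite::write_json(list(r2 = as.list(rep$r2), p = as.list(rep$p)),
                         file.path(out_dir, "variance_partition.json"),
                         auto_unbox = TRUE, digits = NA)
    rep
  })
  files <- c(files, file.path(out_dir, "variance_partition.json"))

  # subgroups
  sg <- stage("subgroups", {
    obs <- observed_subgroup_rates(ds$patients, config$subgroups)
    pred <- predicted_subgroup_rates(trained$holdout$model,
                                     trained$holdout$cohort,
                                     config$subgroups)
    files <- c(files,
                write_stage_csv(obs, out_dir, "observed_subgroup_rates"),
                write_stage_csv(pred, out_dir, "predicted_subgroup_rates"))
    list(observed = obs, predicted = pred)
  })

  manifest <- list(
    seed = config$seed,
    stages = pipeline_stages()[c(TRUE, TRUE, config$selection, TRUE, TRUE,
                                 TRUE, TRUE)],
    out_dir = normalizePath(out_dir),
    files = basename(files),
    checksums = as.list(stats::setNames(unname(tools::md5sum(files)),
                                        basename(files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# default reporting bins per feature for the pipeline's fold-change tables
feature_summary_bins <- function(feature) {
  switch(feature,
         arrival_to_scan = seq(0, 120, 15),
         onset_to_arrival = seq(0, 240, 30),
         nihss = c(0, 5, 10, 15, 20, 25, 30, 43),
         age = c(35, 55, 70, 80, 95),
         NULL)
}

#' Human-readable summary of a completed run
#'
#' Reads a run manifest, verifies that every stage's files are present, and
#' writes a plain-text summary per analysis stage alongside the outputs.
#'
#' @param manifest A manifest returned by [run_all()] (or the path to a
#'   `manifest.json`).
#' @return Character vector of summary lines, invisibly; also written to
#'   `summary.txt` in the run directory.
#' @export
report_run <- function(manifest) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest)
  if (is.null(manifest$out_dir) || is.null(manifest$files)) {
    stop("incomplete run: manifest lacks stages ",
         paste(pipeline_stages(), collapse = ", "))
  }
  missing <- manifest$files[!file.exists(file.path(manifest$out_dir,
                                                   unlist(manifest$files)))]
  if (length(missing)) {
    stop("incomplete run: missing ", paste(unlist(missing), collapse = ", "))
  }
  out_dir <- manifest$out_dir
  lines <- c(sprintf("run seed %s in %s", manifest$seed, out_dir))
  metrics <- jsonlite::read_json(file.path(out_dir, "metrics.json"))
  lines <- c(lines, sprintf(
    "model: accuracy %.3f, ROC AUC %.3f, sens=spec %.3f, hospital r2 %.3f",
    metrics$accuracy, metrics$roc_auc, metrics$balanced_value,
    metrics$hospital_r2))
  vp <- jsonlite::read_json(file.path(out_dir, "variance_partition.json"))
  lines <- c(lines, sprintf(
    "variance explained: patient %.2f, hospital %.2f, combined %.2f",
    vp$r2$patient, vp$r2$hospital, vp$r2$combined))
  cf <- utils::read.csv(file.path(out_dir, "counterfactual_rates.csv"))
  lines <- c(lines, sprintf(
    "counterfactual identical-cohort rate range: %.1f%% to %.1f%%",
    100 * min(cf$predicted_rate), 100 * max(cf$predicted_rate)))
  obs <- utils::read.csv(file.path(out_dir, "observed_subgroup_rates.csv"))
  sm <- summarize_matrix(obs)
  lines <- c(lines, "observed subgroup rates (median across hospitals):",
             sprintf("  %-30s %.3f", sm$subgroup, sm$median))
  writeLines(lines, file.path(out_dir, "summary.txt"))
  invisible(lines)
}
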