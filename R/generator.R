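# Synthetic stroke-audit generator: registry-like patient tables with a known
# additive log-odds decision model and per-hospital propensity offsets.

#' Default per-feature effect shapes of the true decision model
#'
#' Each element parameterises a piecewise-linear effect in log-odds via the
#' fold-changes reported for the national audit: the odds of thrombolysis
#' fall 9-fold over the first 120 min of arrival-to-scan time, rise 30-fold
#' from NIHSS 0 to a 15--25 plateau then fall again, fall 3-fold for
#' estimated (vs precise) onset time, 6-fold from mRS 0 to 5, 5-fold with
#' anticoagulant use, 3-fold between 120 and 240 min onset-to-arrival,
#' 2-fold from age 80 to 110, and 4-fold for onset during sleep.
#'
#' @return Named list of effect-shape parameter lists, one per feature.
#' @export
default_effect_params <- function() {
  list(
    arrival_to_scan   = list(fold_120 = 9, fold_beyond_120 = 2),
    nihss             = list(peak_fold = 30, peak_lo = 15, peak_hi = 25,
                             high_drop_fold = 5),
    precise_onset     = list(fold = 3),
    prior_mrs         = list(fold = 6),
    anticoagulant     = list(fold = 5),
    onset_to_arrival  = list(fold = 3, plateau_min = 120),
    onset_during_sleep = list(fold = 4),
    age               = list(fold = 2, threshold = 80, span_years = 30)
  )
}

#' Configuration of the synthetic stroke-audit generator
#'
#' The defaults are the study conditions used throughout the package: 30
#' stroke teams with on average 700 patients each (the national audit holds
#' 88,928 four-hour arrivals across 132 hospitals, roughly 670 per
#' hospital), a 13-fold extreme odds ratio between hospitals, and the
#' fold-change effect sizes of [default_effect_params()].
#'
#' @param n_hospitals Number of stroke teams.
#' @param patients_per_hospital Mean patients per team; actual team sizes are
#'   proportional to the team's (log-normal) annual admissions.
#' @param seed Master seed; every sampling stage draws from a sub-stream
#'   derived deterministically from it.
#' @param intercept Log-odds intercept of the decision model.
#' @param effect_params Per-feature effect shapes, see
#'   [default_effect_params()].
#' @param hospital_offset_sd Spread of the raw hospital log-odds offsets
#'   before rescaling.
#' @param hospital_offset_span_fold Extreme odds ratio between the most and
#'   least forward-leaning hospitals; offsets are affinely rescaled so the
#'   realised span is exact.
#' @param process_coupling Minutes of median scan-to-needle time removed per
#'   unit of hospital log-odds offset (faster hospitals thrombolyse more).
#' @param arrival_to_scan_location_sd Between-hospital standard deviation of
#'   the additive location shift (minutes) of the arrival-to-scan
#'   distribution.
#' @param prop_haemorrhage Proportion of haemorrhagic strokes.
#' @param prop_precise_onset Proportion with a precisely known onset time.
#' @param prop_anticoagulant Proportion on atrial-fibrillation
#'   anticoagulants.
#' @param prop_sleep_onset Proportion with onset during sleep.
#' @param age_mrs_rho Latent Gaussian-copula correlation between age and
#'   pre-stroke mRS; the default reproduces the audit's reported
#'   age/prior-disability r-squared of about 0.146.
#' @param decoy_feature_count Number of pure-noise decoy features appended
#'   to the table (standard normal, independent of everything).
#'
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_hospitals = 30,
                             patients_per_hospital = 700,
                             seed = 42,
                             intercept = -0.3,
                             effect_params = default_effect_params(),
                             hospital_offset_sd = 0.6,
                             hospital_offset_span_fold = 13,
                             process_coupling = 6,
                             arrival_to_scan_location_sd = 5,
                             prop_haemorrhage = 0.12,
                             prop_precise_onset = 0.7,
                             prop_anticoagulant = 0.12,
                             prop_sleep_onset = 0.08,
                             age_mrs_rho = 0.47,
                             decoy_feature_count = 0) {
  if (!is.numeric(n_hospitals) || length(n_hospitals) != 1 ||
      n_hospitals < 1 || n_hospitals != round(n_hospitals)) {
    stop("invalid generator config: `n_hospitals` must be a positive integer")
  }
  if (!is.numeric(patients_per_hospital) || patients_per_hospital < 1) {
    stop("invalid generator config: `patients_per_hospital` must be >= 1")
  }
  if (hospital_offset_span_fold <= 0) {
    stop("invalid generator config: `hospital_offset_span_fold` must be > 0")
  }
  folds <- unlist(effect_params)
  if (any(!is.finite(folds)) || any(folds[grep("fold", names(folds))] <= 0)) {
    stop("invalid generator config: all effect fold parameters must be > 0")
  }
  cfg <- list(
    n_hospitals = as.integer(n_hospitals),
    patients_per_hospital = patients_per_hospital,
    seed = as.integer(seed),
    intercept = intercept,
    effect_params = effect_params,
    hospital_offset_sd = hospital_offset_sd,
    hospital_offset_span_fold = hospital_offset_span_fold,
    process_coupling = process_coupling,
    arrival_to_scan_location_sd = arrival_to_scan_location_sd,
    prop_haemorrhage = prop_haemorrhage,
    prop_precise_onset = prop_precise_onset,
    prop_anticoagulant = prop_anticoagulant,
    prop_sleep_onset = prop_sleep_onset,
    age_mrs_rho = age_mrs_rho,
    decoy_feature_count = as.integer(decoy_feature_count)
  )
  class(cfg) <- "generator_config"
  cfg
}

# Age-band midpoint grid: 5-year bands from 37.5 to 92.5.
age_band_grid <- function() seq(37.5, 92.5, by = 5)

# Deterministic sub-stream seeds derived from the master seed.
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Sample hospital profiles
#'
#' Draws one profile per stroke team: a ground-truth log-odds propensity
#' offset (affinely rescaled so the extreme odds ratio between teams equals
#' `hospital_offset_span_fold` exactly, and centred to mean zero), annual
#' admissions (log-normal), a median scan-to-needle time negatively coupled
#' to the offset with slope `process_coupling`, and an additive per-team
#' location shift of the arrival-to-scan distribution.
#'
#' @param config A [generator_config()].
#' @return A data.frame with one row per team: `stroke_team`, `true_offset`,
#'   `admissions_per_year`, `median_scan_to_needle_min`,
#'   `arrival_to_scan_location`.
#' @export
sample_hospitals <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  seeds <- derive_seeds(config$seed, 4L)
  n <- config$n_hospitals
  set.seed(seeds[1])
  raw <- stats::rnorm(n, 0, config$hospital_offset_sd)
  if (n == 1 || config$hospital_offset_span_fold == 1 ||
      diff(range(raw)) == 0) {
    offsets <- rep(0, n)
  } else {
    span <- log(config$hospital_offset_span_fold)
    offsets <- raw * span / diff(range(raw))
    offsets <- offsets - mean(offsets)
  }
  admissions <- stats::rlnorm(n, meanlog = log(600), sdlog = 0.35)
  scan_to_needle <- pmax(
    5, 40 - config$process_coupling * offsets + stats::rnorm(n, 0, 8))
  ats_location <- stats::rnorm(n, 0, config$arrival_to_scan_location_sd)
  data.frame(
    stroke_team = sprintf("team_%03d", seq_len(n)),
    true_offset = offsets,
    admissions_per_year = admissions,
    median_scan_to_needle_min = scan_to_needle,
    arrival_to_scan_location = ats_location,
    stringsAsFactors = FALSE
  )
}

#' The ground-truth decision model of the generator
#'
#' Bundles the intercept, the piecewise-linear per-feature effect functions
#' (in log-odds) and the per-hospital offsets. All effects are additive;
#' haemorrhagic stroke is handled deterministically at labelling time, not
#' through a log-odds term.
#'
#' @param config A [generator_config()].
#' @param hospitals Output of [sample_hospitals()].
#' @return Object of class `true_decision_model`.
#' @export
true_decision_model <- function(config, hospitals) {
  ep <- config$effect_params
  effects <- list(
    arrival_to_scan = function(x) {
      -log(ep$arrival_to_scan$fold_120) / 120 * pmin(x, 120) -
        log(ep$arrival_to_scan$fold_beyond_120) / 120 * pmax(0, x - 120)
    },
    nihss = function(x) {
      peak <- log(ep$nihss$peak_fold)
      lo <- ep$nihss$peak_lo
      hi <- ep$nihss$peak_hi
      drop <- log(ep$nihss$high_drop_fold)
      ifelse(x <= lo, peak * x / lo,
             ifelse(x <= hi, peak, peak - drop * (x - hi) / (42 - hi)))
    },
    precise_onset = function(x) -log(ep$precise_onset$fold) * (1 - x),
    prior_mrs = function(x) -log(ep$prior_mrs$fold) * x / 5,
    anticoagulant = function(x) -log(ep$anticoagulant$fold) * x,
    onset_to_arrival = function(x) {
      p <- ep$onset_to_arrival$plateau_min
      -log(ep$onset_to_arrival$fold) * pmax(0, x - p) / (240 - p)
    },
    onset_during_sleep = function(x) -log(ep$onset_during_sleep$fold) * x,
    age = function(x) {
      -log(ep$age$fold) *
        pmax(0, x - ep$age$threshold) / ep$age$span_years
    }
  )
  model <- list(
    intercept = config$intercept,
    effects = effects,
    offsets = stats::setNames(hospitals$true_offset, hospitals$stroke_team),
    interactions = list()
  )
  class(model) <- "true_decision_model"
  model
}

# Domain checks shared by true_log_odds and table validation.
feature_domains <- function() {
  list(
    arrival_to_scan = function(x) is.numeric(x) & x >= 0,
    infarction = function(x) x %in% c(0, 1),
    nihss = function(x) x %in% 0:42,
    precise_onset = function(x) x %in% c(0, 1),
    prior_mrs = function(x) x %in% 0:5,
    anticoagulant = function(x) x %in% c(0, 1),
    onset_to_arrival = function(x) is.numeric(x) & x > 0 & x <= 240,
    onset_during_sleep = function(x) x %in% c(0, 1),
    age = function(x) x %in% age_band_grid()
  )
}

#' True log-odds of thrombolysis under the generator's decision model
#'
#' Additive and deterministic: intercept + per-feature effects + hospital
#' offset (+ any configured interaction terms). Defined for infarction
#' records only; haemorrhagic stroke is excluded deterministically at
#' labelling time.
#'
#' @param records Data.frame of patient records (infarction == 1 rows).
#' @param model A [true_decision_model()].
#' @return Numeric vector of log-odds, one per record.
#' @export
true_log_odds <- function(records, model) {
  stopifnot(inherits(model, "true_decision_model"))
  if (any(records$infarction != 1)) {
    stop("true_log_odds is defined for infarction records only ",
         "(haemorrhage is excluded deterministically at labelling)")
  }
  doms <- feature_domains()
  for (f in names(doms)) {
    if (!all(doms[[f]](records[[f]]))) {
      stop("feature `", f, "` outside its declared domain")
    }
  }
  if (!all(records$stroke_team %in% names(model$offsets))) {
    stop("unknown `stroke_team` in records")
  }
  lo <- model$intercept + model$offsets[records$stroke_team]
  for (f in names(model$effects)) {
    lo <- lo + model$effects[[f]](records[[f]])
  }
  for (g in model$interactions) lo <- lo + g(records)
  unname(lo)
}

#' Sample unlabelled patient records
#'
#' One row per patient: team assignment proportional to admissions, feature
#' marginals independent except a latent Gaussian-copula dependence between
#' age band and pre-stroke mRS, per-team location shift of arrival-to-scan
#' time, and optional pure-noise decoy columns.
#'
#' @param config A [generator_config()].
#' @param hospitals Output of [sample_hospitals()].
#' @param n_total Optional total row count; defaults to
#'   `n_hospitals * patients_per_hospital` split proportionally to
#'   admissions.
#' @return Data.frame of patient records without the label column.
#' @export
sample_patients <- function(config, hospitals, n_total = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (nrow(hospitals) == 0) stop("empty hospital list")
  seeds <- derive_seeds(config$seed, 4L)
  set.seed(seeds[2])
  if (is.null(n_total)) {
    n_total <- round(config$n_hospitals * config$patients_per_hospital)
  }
  n_total <- as.integer(n_total)
  if (n_total == 0) {
    return(empty_patient_table(config$decoy_feature_count))
  }
  w <- hospitals$admissions_per_year / sum(hospitals$admissions_per_year)
  team_idx <- sample.int(nrow(hospitals), n_total, replace = TRUE, prob = w)
  team <- hospitals$stroke_team[team_idx]

  ats <- stats::rlnorm(n_total, meanlog = log(32), sdlog = 0.85) +
    hospitals$arrival_to_scan_location[team_idx]
  ats <- pmin(pmax(ats, 1), 600)

  infarction <- stats::rbinom(n_total, 1, 1 - config$prop_haemorrhage)
  nihss <- pmin(floor(stats::rgamma(n_total, shape = 1.8, scale = 4.5)), 42)
  precise <- stats::rbinom(n_total, 1, config$prop_precise_onset)

  # age and prior mRS from a Gaussian copula so that their r-squared matches
  # the audit's reported 0.146 at the default rho
  grid <- age_band_grid()
  age_w <- stats::dnorm(grid, 74, 11.5)
  age_p <- age_w / sum(age_w)
  z_age <- stats::rnorm(n_total)
  age_breaks <- stats::qnorm(cumsum(age_p)[-length(age_p)])
  age <- grid[findInterval(z_age, age_breaks) + 1L]
  rho <- config$age_mrs_rho
  z_mrs <- rho * z_age + sqrt(1 - rho^2) * stats::rnorm(n_total)
  mrs_p <- c(0.55, 0.17, 0.10, 0.08, 0.06, 0.04)
  mrs_breaks <- stats::qnorm(cumsum(mrs_p)[-6])
  mrs <- findInterval(z_mrs, mrs_breaks)

  anticoag <- stats::rbinom(n_total, 1, config$prop_anticoagulant)
  # onset-to-arrival: log-normal truncated to the 4 h audit window
  u <- stats::runif(n_total)
  ota <- stats::qlnorm(u * stats::plnorm(240, log(95), 0.55),
                       meanlog = log(95), sdlog = 0.55)
  ota <- pmin(pmax(ota, 1), 240)
  sleep <- stats::rbinom(n_total, 1, config$prop_sleep_onset)

  out <- data.frame(
    arrival_to_scan = ats,
    infarction = infarction,
    nihss = as.integer(nihss),
    precise_onset = precise,
    prior_mrs = as.integer(mrs),
    stroke_team = team,
    anticoagulant = anticoag,
    onset_to_arrival = ota,
    onset_during_sleep = sleep,
    age = age,
    stringsAsFactors = FALSE
  )
  if (config$decoy_feature_count > 0) {
    set.seed(seeds[3])
    for (k in seq_len(config$decoy_feature_count)) {
      out[[sprintf("decoy_%02d", k)]] <- stats::rnorm(n_total)
    }
  }
  out
}

empty_patient_table <- function(decoy_feature_count = 0, label = FALSE) {
  out <- data.frame(
    arrival_to_scan = numeric(0), infarction = numeric(0),
    nihss = integer(0), precise_onset = numeric(0), prior_mrs = integer(0),
    stroke_team = character(0), anticoagulant = numeric(0),
    onset_to_arrival = numeric(0), onset_during_sleep = numeric(0),
    age = numeric(0), stringsAsFactors = FALSE
  )
  for (k in seq_len(decoy_feature_count)) {
    out[[sprintf("decoy_%02d", k)]] <- numeric(0)
  }
  if (label) out$thrombolysis <- numeric(0)
  out
}

#' Assign thrombolysis labels
#'
#' Haemorrhagic stroke is never thrombolysed (deterministic label 0);
#' infarction labels are Bernoulli draws from the logistic of the true
#' log-odds.
#'
#' @param table Unlabelled patient table from [sample_patients()].
#' @param model A [true_decision_model()].
#' @param seed Integer seed for the label draws.
#' @return The table with a `thrombolysis` column appended.
#' @export
assign_labels <- function(table, model, seed) {
  y <- integer(nrow(table))
  inf <- table$infarction == 1
  if (any(inf)) {
    lo <- true_log_odds(table[inf, , drop = FALSE], model)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    y[inf] <- stats::rbinom(sum(inf), 1, stats::plogis(lo))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  table$thrombolysis <- y
  table
}

#' Generate a complete labelled synthetic dataset
#'
#' Convenience wrapper: hospitals, patients, true decision model and labels
#' in one call, all driven by the config's master seed.
#'
#' @param config A [generator_config()].
#' @return List with elements `patients` (labelled table), `hospitals`,
#'   `model` (the ground-truth decision model) and `config`.
#' @export
generate_dataset <- function(config = generator_config()) {
  hospitals <- sample_hospitals(config)
  model <- true_decision_model(config, hospitals)
  patients <- sample_patients(config, hospitals)
  seeds <- derive_seeds(config$seed, 4L)
  patients <- assign_labels(patients, model, seeds[4])
  list(patients = patients, hospitals = hospitals, model = model,
       config = config)
}
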