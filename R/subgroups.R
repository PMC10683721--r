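# Observed and counterfactually predicted thrombolysis rates for clinically
# defined patient subgroups at every hospital.

#' The eleven built-in patient subgroups
#'
#' One "ideally thrombolysable" subgroup (all nine favourable feature
#' values at once), nine single-feature sub-optimal subgroups, and one
#' combined two-feature subgroup (low severity with estimated onset time).
#' Interval bins are half-open (`[60, 90)` minutes) to avoid double
#' counting; "NIHSS in range 10--25" is inclusive; "age 80+" means an
#' age-band midpoint of 80 or above.
#'
#' @return Named list of `subgroup_definition` objects (`name`,
#'   `predicate`).
#' @export
builtin_subgroups <- function() {
  def <- function(name, predicate) {
    structure(list(name = name, predicate = predicate),
              class = "subgroup_definition")
  }
  defs <- list(
    def("ideal", function(p) {
      p$infarction == 1 & p$arrival_to_scan < 30 &
        p$nihss >= 10 & p$nihss <= 25 & p$precise_onset == 1 &
        p$prior_mrs == 0 & p$anticoagulant == 0 &
        p$onset_to_arrival < 90 & p$age < 80 & p$onset_during_sleep == 0
    }),
    def("haemorrhagic", function(p) p$infarction == 0),
    def("arrival_to_scan_60_90", function(p) {
      p$arrival_to_scan >= 60 & p$arrival_to_scan < 90
    }),
    def("nihss_below_5", function(p) p$nihss < 5),
    def("estimated_onset", function(p) p$precise_onset == 0),
    def("prior_disability", function(p) p$prior_mrs > 2),
    def("anticoagulant_use", function(p) p$anticoagulant == 1),
    def("onset_to_arrival_150_180", function(p) {
      p$onset_to_arrival >= 150 & p$onset_to_arrival < 180
    }),
    def("age_80_plus", function(p) p$age >= 80),
    def("sleep_onset", function(p) p$onset_during_sleep == 1),
    def("nihss_below_5_estimated_onset", function(p) {
      p$nihss < 5 & p$precise_onset == 0
    })
  )
  stats::setNames(defs, vapply(defs, `[[`, "", "name"))
}

subgroup_membership <- function(table, subgroups) {
  memb <- vapply(subgroups, function(sg) sg$predicate(table),
                 logical(nrow(table)))
  if (!is.matrix(memb)) {
    memb <- matrix(memb, nrow = nrow(table),
                   dimnames = list(NULL, names(subgroups)))
  }
  memb
}

#' Observed thrombolysis rates per hospital and subgroup
#'
#' Rate = thrombolysed / subgroup count within each hospital. Cells with
#' fewer than `min_count` patients are reported with `rate = NA` (the count
#' is always reported alongside).
#'
#' @param table Labelled patient table.
#' @param subgroups List of subgroup definitions
#'   ([builtin_subgroups()] by default).
#' @param min_count Minimum cell count for a reported rate.
#' @return Tidy data.frame: `stroke_team`, `subgroup`, `n`, `events`,
#'   `rate`.
#' @export
observed_subgroup_rates <- function(table, subgroups = builtin_subgroups(),
                                    min_count = 5) {
  memb <- subgroup_membership(table, subgroups)
  teams <- sort(unique(as.character(table$stroke_team)))
  rows <- lapply(names(subgroups), function(sg) {
    inn <- memb[, sg]
    n <- table(factor(table$stroke_team[inn], teams))
    ev <- tapply(table$thrombolysis[inn],
                 factor(table$stroke_team[inn], teams), sum)
    ev[is.na(ev)] <- 0
    data.frame(stroke_team = teams, subgroup = sg, n = as.integer(n),
               events = as.integer(ev),
               rate = ifelse(n >= min_count, as.integer(ev) / as.integer(n),
                             NA_real_),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Predicted subgroup thrombolysis rates under the counterfactual cohort
#'
#' Assigns the full held-out cohort to each hospital in turn (rewriting the
#' hospital encoding), predicts thrombolysis probabilities with the holdout
#' model, and averages them within each subgroup: the rate each hospital
#' would be predicted to deliver to an identical set of patients.
#'
#' @param model The holdout `tv_model`.
#' @param cohort Held-out patient table.
#' @param subgroups List of subgroup definitions.
#' @param teams Hospitals to cycle through; defaults to the model encoding.
#' @param min_count Minimum subgroup size in the cohort for a reported
#'   rate.
#' @return Tidy data.frame: `stroke_team`, `subgroup`, `n`, `rate`.
#' @export
predicted_subgroup_rates <- function(model, cohort,
                                     subgroups = builtin_subgroups(),
                                     teams = NULL, min_count = 1) {
  if (is.null(teams)) teams <- model$encoding$teams
  memb <- subgroup_membership(cohort, subgroups)
  enc <- encode_features(cohort, model$encoding)
  has_team <- any(grepl("^team::", model$feature_names))
  rows <- lapply(teams, function(h) {
    xh <- if (has_team) set_team(enc$x, h, model$encoding) else enc$x
    pr <- stats::predict(model$booster,
                         xh[, model$feature_names, drop = FALSE])
    n <- colSums(memb)
    rate <- vapply(colnames(memb), function(sg) {
      if (n[sg] >= min_count && n[sg] > 0) mean(pr[memb[, sg]]) else NA_real_
    }, 0)
    data.frame(stroke_team = h, subgroup = colnames(memb),
               n = as.integer(n), rate = as.numeric(rate),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Five-number summaries of a hospital-by-subgroup rate matrix
#'
#' Quartiles of the per-hospital rates within each subgroup, missing cells
#' excluded; a subgroup with no reportable cells is flagged missing.
#'
#' @param rates Tidy rate table from [observed_subgroup_rates()] or
#'   [predicted_subgroup_rates()].
#' @return Data.frame: `subgroup`, `n_hospitals`, `min`, `q25`, `median`,
#'   `q75`, `max`.
#' @export
summarize_matrix <- function(rates) {
  rows <- lapply(split(rates, rates$subgroup), function(d) {
    ok <- !is.na(d$rate)
    if (!any(ok)) {
      return(data.frame(subgroup = d$subgroup[1], n_hospitals = 0L,
                        min = NA_real_, q25 = NA_real_, median = NA_real_,
                        q75 = NA_real_, max = NA_real_,
                        stringsAsFactors = FALSE))
    }
    q <- stats::quantile(d$rate[ok], c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(subgroup = d$subgroup[1], n_hospitals = sum(ok),
               min = q[1], q25 = q[2], median = q[3], q75 = q[4], max = q[5],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[match(unique(rates$subgroup), out$subgroup), , drop = FALSE]
}
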