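test_that("generator config validates its inputs", {
  expect_error(generator_config(n_hospitals = 0), "n_hospitals")
  expect_error(generator_config(patients_per_hospital = 0),
               "patients_per_hospital")
  expect_error(generator_config(hospital_offset_span_fold = 0), "span_fold")
  ep <- default_effect_params()
  ep$precise_onset$fold <- -1
  expect_error(generator_config(effect_params = ep), "fold")
})

test_that("generation is deterministic given the master seed", {
  cfg <- generator_config(n_hospitals = 3, patients_per_hospital = 60,
                          seed = 5)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$patients, d2$patients)
  expect_identical(d1$hospitals, d2$hospitals)
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_dataset(d1$patients, f1)
  write_dataset(d2$patients, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("hospital offsets span the configured odds ratio exactly", {
  h <- sample_hospitals(generator_config(n_hospitals = 30, seed = 2))
  expect_equal(exp(diff(range(h$true_offset))), 13, tolerance = 1e-9)
  expect_equal(mean(h$true_offset), 0, tolerance = 1e-12)
  expect_false(anyDuplicated(h$stroke_team) > 0)

  h1 <- sample_hospitals(generator_config(n_hospitals = 1))
  expect_identical(h1$true_offset, 0)
})

test_that("process descriptors couple to the offset as configured", {
  h0 <- sample_hospitals(generator_config(n_hospitals = 1000,
                                          process_coupling = 0, seed = 3))
  expect_lt(abs(cor(h0$true_offset, h0$median_scan_to_needle_min)), 0.1)
  hn <- sample_hospitals(generator_config(n_hospitals = 200,
                                          process_coupling = 12, seed = 3))
  expect_lt(cor(hn$true_offset, hn$median_scan_to_needle_min), 0)
})

test_that("true log-odds is additive with hand-checkable piecewise terms", {
  cfg <- generator_config(n_hospitals = 2, seed = 4)
  h <- sample_hospitals(cfg)
  m <- true_decision_model(cfg, h)
  rec <- data.frame(arrival_to_scan = 60, infarction = 1, nihss = 20L,
                    precise_onset = 0, prior_mrs = 2L,
                    stroke_team = h$stroke_team[1], anticoagulant = 1,
                    onset_to_arrival = 180, onset_during_sleep = 1,
                    age = 87.5, stringsAsFactors = FALSE)
  # independent hand ledger: every term written out from the fold spans
  expected <- cfg$intercept + h$true_offset[1] +
    (-log(9) / 120 * 60) +        # arrival-to-scan, first 120 min
    log(30) +                     # NIHSS 20: on the 15-25 plateau
    (-log(3)) +                   # estimated onset time
    (-log(6) * 2 / 5) +           # prior mRS 2 of 5
    (-log(5)) +                   # anticoagulant use
    (-log(3) * (180 - 120) / 120) + # onset-to-arrival beyond 120 min
    (-log(4)) +                   # onset during sleep
    (-log(2) * 7.5 / 30)          # age 87.5, decline past 80
  expect_equal(true_log_odds(rec, m), expected, tolerance = 1e-12)

  rec2 <- rec
  rec2$stroke_team <- h$stroke_team[2]
  expect_equal(true_log_odds(rec2, m) - true_log_odds(rec, m),
               h$true_offset[2] - h$true_offset[1], tolerance = 1e-12)

  r0 <- rec; r0$arrival_to_scan <- 0
  r120 <- rec; r120$arrival_to_scan <- 120
  expect_equal(true_log_odds(r0, m) - true_log_odds(r120, m), log(9),
               tolerance = 1e-12)

  bad <- rec; bad$nihss <- 50L
  expect_error(true_log_odds(bad, m), "nihss")
  haem <- rec; haem$infarction <- 0
  expect_error(true_log_odds(haem, m), "infarction")
})

test_that("labelling is Bernoulli-consistent and excludes haemorrhage", {
  d <- small_dataset()
  p <- d$patients
  expect_true(all(p$thrombolysis[p$infarction == 0] == 0))

  inf <- p[p$infarction == 1, ]
  pr <- stats::plogis(true_log_odds(inf, d$model))
  se <- sqrt(sum(pr * (1 - pr))) / nrow(inf)
  expect_lt(abs(mean(inf$thrombolysis) - mean(pr)), 3 * se)

  # a record with exactly zero log-odds is thrombolysed half the time
  ep <- default_effect_params()
  ep$arrival_to_scan$fold_120 <- 1
  ep$arrival_to_scan$fold_beyond_120 <- 1
  ep$nihss$peak_fold <- 1
  ep$nihss$high_drop_fold <- 1
  ep$precise_onset$fold <- 1
  ep$prior_mrs$fold <- 1
  ep$anticoagulant$fold <- 1
  ep$onset_to_arrival$fold <- 1
  ep$onset_during_sleep$fold <- 1
  ep$age$fold <- 1
  cfg0 <- generator_config(n_hospitals = 1, intercept = 0,
                           effect_params = ep,
                           hospital_offset_span_fold = 1)
  h0 <- sample_hospitals(cfg0)
  m0 <- true_decision_model(cfg0, h0)
  rec <- data.frame(arrival_to_scan = 30, infarction = 1, nihss = 10L,
                    precise_onset = 1, prior_mrs = 1L,
                    stroke_team = h0$stroke_team[1], anticoagulant = 0,
                    onset_to_arrival = 100, onset_during_sleep = 0,
                    age = 67.5, stringsAsFactors = FALSE)
  expect_equal(true_log_odds(rec, m0), 0, tolerance = 1e-12)
  tab <- rec[rep(1, 10000), ]
  lab <- assign_labels(tab, m0, seed = 99)
  expect_lt(abs(mean(lab$thrombolysis) - 0.5), 0.015)

  # an all-haemorrhage table is never thrombolysed
  haem_tab <- p[p$infarction == 0, setdiff(names(p), "thrombolysis")]
  expect_true(all(assign_labels(haem_tab, d$model, 1)$thrombolysis == 0))
})

test_that("sampled patients respect the audit domains and marginals", {
  d <- small_dataset()
  p <- d$patients
  expect_true(all(p$onset_to_arrival > 0 & p$onset_to_arrival <= 240))
  expect_true(all(p$nihss %in% 0:42))
  expect_true(all(p$age %in% seq(37.5, 92.5, 5)))
  expect_true(all(p$prior_mrs %in% 0:5))
  expect_true(all(p$arrival_to_scan >= 0))
  expect_setequal(unique(p$stroke_team), d$hospitals$stroke_team)

  big <- generate_dataset(generator_config(n_hospitals = 30,
                                           patients_per_hospital = 667,
                                           seed = 1))$patients
  prop <- d$config$prop_haemorrhage
  se <- sqrt(prop * (1 - prop) / nrow(big))
  expect_lt(abs(mean(big$infarction == 0) - prop), 2 * se)

  # overall label rate lands in a plausible audit range
  expect_gt(mean(p$thrombolysis), 0.25)
  expect_lt(mean(p$thrombolysis), 0.45)
})

test_that("an empty patient request returns the full column schema", {
  cfg <- generator_config(n_hospitals = 2, decoy_feature_count = 1)
  h <- sample_hospitals(cfg)
  e <- sample_patients(cfg, h, n_total = 0)
  expect_identical(nrow(e), 0L)
  expect_identical(names(e), c(patient_schema_columns(), "decoy_01"))
})

test_that("decoy features are emitted and pure noise", {
  d <- generate_dataset(generator_config(n_hospitals = 4,
                                         patients_per_hospital = 150,
                                         seed = 13, decoy_feature_count = 3))
  p <- d$patients
  expect_true(all(c("decoy_01", "decoy_02", "decoy_03") %in% names(p)))
  for (k in paste0("decoy_0", 1:3)) {
    expect_lt(abs(cor(p[[k]], p$thrombolysis)), 0.1)
  }
})
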