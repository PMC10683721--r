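test_that("team encoding is one-hot, invertible and guards unseen teams", {
  d <- small_dataset()$patients
  enc <- encode_features(d)
  teamcols <- grep("^team::", colnames(enc$x))
  expect_identical(length(teamcols), 8L)
  expect_true(all(rowSums(enc$x[, teamcols]) == 1))
  expect_false("thrombolysis" %in% colnames(enc$x))

  dec <- decode_features(enc$x, enc$encoding)
  expect_identical(dec$stroke_team, as.character(d$stroke_team))
  expect_equal(dec$nihss, as.numeric(d$nihss))

  # move a row to another team and back: original row restored
  orig_team <- as.character(d$stroke_team[1])
  other <- setdiff(enc$encoding$teams, orig_team)[1]
  x1 <- set_team(enc$x[1, , drop = FALSE], other, enc$encoding)
  expect_false(identical(x1, enc$x[1, , drop = FALSE]))
  x1b <- set_team(x1, orig_team, enc$encoding)
  expect_identical(x1b, enc$x[1, , drop = FALSE])

  d_bad <- d[1:3, ]
  d_bad$stroke_team <- "team_999"
  expect_error(encode_features(d_bad, enc$encoding), "unseen")
  expect_error(set_team(enc$x, "team_999", enc$encoding), "unseen")
})

test_that("a 132-team table encodes to 9 numeric plus 132 indicators", {
  teams <- sprintf("t%03d", 1:132)
  d <- small_dataset()$patients[rep(1:50, length.out = 264), ]
  d$stroke_team <- rep(teams, each = 2)
  enc <- encode_features(d)
  expect_identical(ncol(enc$x), 9L + 132L)
})

test_that("k-fold training partitions rows and predicts each exactly once", {
  d <- small_dataset()$patients
  kf <- fit_kfold(d, small_config("kfold", n_folds = 4, nrounds = 40))
  expect_identical(sort(unique(kf$fold)), 1:4)
  expect_identical(length(kf$fold), nrow(d))
  expect_true(all(kf$oof_prob > 0 & kf$oof_prob < 1))
  # stratification: fold label rates all close to the overall rate
  rates <- tapply(d$thrombolysis, kf$fold, mean)
  expect_lt(diff(range(rates)), 0.02)

  m <- kf$models[[1]]
  pr <- predict(m, d)
  mg <- predict(m, d, type = "margin")
  expect_lt(max(abs(stats::plogis(mg) - pr)), 1e-6)
})

test_that("a separable decision rule is learned almost perfectly", {
  d <- small_dataset()$patients
  d$thrombolysis <- as.integer(d$infarction == 1 & d$nihss >= 10)
  kf <- fit_kfold(d, small_config("kfold", nrounds = 30))
  expect_gt(kf$metrics$accuracy, 0.99)
})

test_that("labels shuffled against features give chance-level AUC", {
  d <- generate_dataset(generator_config(seed = 11))$patients
  d <- d[d$infarction == 1, ]  # haemorrhage labels are structurally 0
  set.seed(42)
  d$thrombolysis <- sample(d$thrombolysis)
  kf <- fit_kfold(d, model_config("kfold", nrounds = 30, max_depth = 3,
                                  seed = 11))
  expect_lt(abs(kf$metrics$roc_auc - 0.5), 0.02)
})

test_that("holdout cohort is disjoint, stratified and reproducible", {
  d <- small_dataset()$patients
  hold <- small_holdout()
  expect_identical(length(intersect(hold$holdout_idx,
                                    hold$model$train_idx)), 0L)
  expect_identical(nrow(hold$cohort), 400L)
  expect_identical(sort(c(hold$holdout_idx, hold$model$train_idx)),
                   seq_len(nrow(d)))

  hold2 <- fit_holdout(d, small_config("holdout", holdout_size = 400))
  expect_identical(hold2$holdout_idx, hold$holdout_idx)

  # stratified draw keeps the cohort label rate at the table's rate
  p_all <- mean(d$thrombolysis)
  m <- nrow(hold$cohort)
  se <- sqrt(p_all * (1 - p_all) / m * (1 - m / nrow(d)))
  expect_lt(abs(mean(hold$cohort$thrombolysis) - p_all), 3 * se + 1 / m)

  expect_error(fit_holdout(d, small_config("holdout", holdout_size = 5000)),
               "holdout_size")
})

test_that("hospital-blind training drops the indicator block", {
  d <- small_dataset()$patients
  feats <- setdiff(names(d), c("thrombolysis", "stroke_team"))
  m0 <- fit_all_data(d, small_config(nrounds = 30), features = feats)
  expect_false(any(grepl("^team::", m0$feature_names)))
  expect_identical(length(predict(m0, d)), nrow(d))
})
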