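test_that("a single stump attributes (1-p)(a-b) to its split feature", {
  set.seed(9)
  n <- 200
  x <- cbind(f1 = stats::rnorm(n), f2 = stats::rnorm(n))
  y <- ifelse(x[, "f1"] < 0, 1, -1) + stats::rnorm(n) * 0.1
  bst <- xgboost::xgb.train(
    params = list(objective = "reg:squarederror", max_depth = 1, eta = 1,
                  nthread = 1, tree_method = "exact", base_score = 0),
    data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
    nrounds = 1, verbose = 0)
  tree <- as.data.frame(xgboost::xgb.model.dt.tree(bst))
  expect_identical(tree$Feature[1], "f1")
  a <- tree$Gain[tree$ID == tree$Yes[1]]
  b <- tree$Gain[tree$ID == tree$No[1]]
  p <- tree$Cover[tree$ID == tree$Yes[1]] / tree$Cover[1]

  ctr <- stats::predict(bst, x, predcontrib = TRUE)
  left <- x[, "f1"] < tree$Split[1]
  expect_equal(unique(round(ctr[left, "f1"], 6)),
               round((1 - p) * (a - b), 6))
  expect_equal(unique(round(ctr[!left, "f1"], 6)),
               round(p * (b - a), 6))
  # the non-split feature gets nothing
  expect_lt(max(abs(ctr[, "f2"])), 1e-7)
})

test_that("SHAP additivity holds and the team block aggregates correctly", {
  d <- small_dataset()$patients
  sh <- small_shap()
  expect_lt(max(abs(sh$base + rowSums(sh$values) - sh$margin)), 1e-3)
  expect_identical(ncol(sh$values), 10L)
  expect_true("stroke_team" %in% colnames(sh$values))

  # team block aggregation equals the sum of the raw indicator contributions
  fit <- small_all_fit()
  x <- encode_features(d, fit$encoding)$x[, fit$feature_names, drop = FALSE]
  ctr <- stats::predict(fit$booster, x, predcontrib = TRUE)
  raw_team <- rowSums(ctr[, grep("^team::", colnames(ctr)), drop = FALSE])
  expect_equal(sh$values[, "stroke_team"], raw_team, tolerance = 1e-9)
})

test_that("depth-1 ensembles produce no pairwise interactions", {
  d <- small_dataset()$patients[1:300, ]
  m <- fit_all_data(small_dataset()$patients,
                    model_config("all_data", nrounds = 30, max_depth = 1,
                                 seed = 7))
  tens <- compute_interactions(m, d)
  offdiag <- tens$values
  for (i in seq_along(tens$features)) offdiag[, i, i] <- 0
  # the aggregated team pseudo-feature keeps its within-block terms; all
  # true feature pairs must be zero
  offdiag[, "stroke_team", "stroke_team"] <- 0
  expect_lt(max(abs(offdiag)), 1e-6)
})

test_that("interaction row sums reproduce total SHAP values", {
  sh <- small_shap()
  tens <- small_tensor()
  expect_lt(max(abs(tensor_row_sums(tens) - sh$values)), 1e-3)
  expect_lt(max(abs(tens$values - aperm(tens$values, c(1, 3, 2)))), 1e-5)
})

test_that("subset SHAP reduces to totals and main effects at the extremes", {
  tens <- small_tensor()
  all_in_one <- subset_shap(tens, list(everything = tens$features))
  expect_equal(all_in_one$values, tensor_row_sums(tens), tolerance = 1e-12)

  singles <- subset_shap(tens, as.list(stats::setNames(tens$features,
                                                       tens$features)))
  diag_vals <- sapply(seq_along(tens$features),
                      function(i) tens$values[, i, i])
  colnames(diag_vals) <- tens$features
  expect_equal(singles$values, diag_vals, tolerance = 1e-12)

  expect_error(subset_shap(tens, list(a = "nihss")), "missing")
  expect_error(
    subset_shap(tens, list(a = tens$features, b = "nihss")), "disjoint")
})

test_that("waterfalls walk from the base rate to the predicted probability", {
  sh <- small_shap()
  flat <- waterfall(stats::setNames(rep(0, 5), paste0("f", 1:5)), sh$base[1])
  expect_true(all(flat$cumulative_probability ==
                    stats::plogis(sh$base[1])))

  for (i in c(1, 50, 200)) {
    w <- waterfall(sh$values[i, ], sh$base[i])
    expect_equal(w$cumulative_probability[nrow(w)],
                 stats::plogis(sh$margin[i]), tolerance = 1e-6)
    expect_true(all(diff(abs(w$contribution)) <= 1e-12))
  }
})

test_that("binned SHAP summaries recover the shape of the true effects", {
  d <- small_dataset()$patients
  sh <- small_shap()
  s <- shap_vs_value_summary(d, sh, "arrival_to_scan", bins = seq(0, 120, 30))
  expect_true(all(diff(s$median) < 0))  # monotone decline
  expect_equal(fold_change(s, s$bin[1], s$bin[1]), 1.0)

  # haemorrhagic stroke is pushed hard towards never-thrombolyse
  haem <- d$infarction == 0
  expect_lt(stats::median(sh$values[haem, "infarction"]), -1)

  s2 <- shap_vs_value_summary(d, sh, "nihss", bins = c(0, 5, 10, 43))
  expect_error(fold_change(s2, "nope", s2$bin[1]), "not found")
  toy_tab <- data.frame(v = c(1, 2, 3))
  toy_sh <- structure(list(values = matrix(c(0.1, 0.2, 0.3), 3,
                                           dimnames = list(NULL, "v")),
                           base = rep(0, 3), margin = rep(0, 3),
                           features = "v"),
                      class = "shap_matrix")
  expect_warning(shap_vs_value_summary(toy_tab, toy_sh, "v",
                                       bins = c(0, 5, 10)),
                 "empty")
})

test_that("span-based fold changes recover the generator's odds spans", {
  d <- small_dataset()$patients
  sh <- small_shap()
  fc <- fold_change_span(d, sh, "arrival_to_scan", from = 0, to = 120)
  expect_gt(fc, 3)
  expect_lt(fc, 20)
  slp <- shap_vs_value_summary(d, sh, "onset_during_sleep")
  expect_gt(fold_change(slp, "0", "1"), 2)
})
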