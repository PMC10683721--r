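test_that("exactly eleven subgroups with the stated clinical bounds", {
  sgs <- builtin_subgroups()
  expect_identical(length(sgs), 11L)

  # NIHSS 4 with estimated onset matches three subgroups
  rec <- data.frame(arrival_to_scan = 20, infarction = 1, nihss = 4L,
                    precise_onset = 0, prior_mrs = 0L, stroke_team = "h1",
                    anticoagulant = 0, onset_to_arrival = 60,
                    onset_during_sleep = 0, age = 67.5,
                    stringsAsFactors = FALSE)
  memb <- thrombovar:::subgroup_membership(rec, sgs)
  expect_setequal(colnames(memb)[memb[1, ]],
                  c("nihss_below_5", "estimated_onset",
                    "nihss_below_5_estimated_onset"))

  # an ideal record matches only the ideal subgroup
  ideal <- data.frame(arrival_to_scan = 20, infarction = 1, nihss = 15L,
                      precise_onset = 1, prior_mrs = 0L, stroke_team = "h1",
                      anticoagulant = 0, onset_to_arrival = 60,
                      onset_during_sleep = 0, age = 67.5,
                      stringsAsFactors = FALSE)
  memb2 <- thrombovar:::subgroup_membership(ideal, sgs)
  expect_identical(colnames(memb2)[memb2[1, ]], "ideal")

  # interval conventions: half-open scan bin, midpoint age grid
  edge <- ideal
  edge$arrival_to_scan <- 90
  expect_false(thrombovar:::subgroup_membership(
    edge, sgs)[1, "arrival_to_scan_60_90"])
  old <- ideal
  old$age <- 82.5
  expect_true(thrombovar:::subgroup_membership(old, sgs)[1, "age_80_plus"])
})

test_that("observed subgroup rates are plain arithmetic with count flags", {
  tab <- data.frame(
    arrival_to_scan = c(10, 20, 70, 80), infarction = 1, nihss = c(2L, 3L, 12L, 20L),
    precise_onset = 1, prior_mrs = 0L, stroke_team = "h1", anticoagulant = 0,
    onset_to_arrival = 60, onset_during_sleep = 0, age = 67.5,
    thrombolysis = c(1L, 0L, 1L, 1L), stringsAsFactors = FALSE)
  r <- observed_subgroup_rates(tab, min_count = 1)
  low <- r[r$subgroup == "nihss_below_5", ]
  expect_identical(low$n, 2L)
  expect_identical(low$events, 1L)
  expect_equal(low$rate, 0.5)

  # below the minimum count the rate is withheld but the count reported
  r5 <- observed_subgroup_rates(tab, min_count = 5)
  expect_true(is.na(r5$rate[r5$subgroup == "nihss_below_5"]))
  expect_identical(r5$n[r5$subgroup == "nihss_below_5"], 2L)

  # haemorrhagic subgroup rate is zero wherever it is reportable
  d <- small_dataset()$patients
  rr <- observed_subgroup_rates(d)
  haem <- rr[rr$subgroup == "haemorrhagic" & !is.na(rr$rate), ]
  expect_true(all(haem$rate == 0))
})

test_that("predicted subgroup rates flag empty cells and follow observed", {
  d <- small_dataset()
  hold <- small_holdout()
  pred <- predicted_subgroup_rates(hold$model, hold$cohort)
  expect_identical(sort(unique(pred$stroke_team)),
                   sort(d$hospitals$stroke_team))

  # a subgroup matching no cohort rows is flagged missing
  none <- list(impossible = structure(
    list(name = "impossible",
         predicate = function(p) p$nihss > 100),
    class = "subgroup_definition"))
  p0 <- predicted_subgroup_rates(hold$model, hold$cohort, subgroups = none)
  expect_true(all(is.na(p0$rate)))
  expect_true(all(p0$n == 0L))

  # observed and predicted medians rank the subgroups the same way
  obs_sum <- summarize_matrix(observed_subgroup_rates(d$patients))
  pred_sum <- summarize_matrix(pred)
  shared <- intersect(obs_sum$subgroup[!is.na(obs_sum$median)],
                      pred_sum$subgroup[!is.na(pred_sum$median)])
  expect_gt(cor(obs_sum$median[match(shared, obs_sum$subgroup)],
                pred_sum$median[match(shared, pred_sum$subgroup)],
                method = "spearman"), 0.9)
})

test_that("matrix summaries are five-number and robust to gaps", {
  r <- data.frame(stroke_team = rep(c("a", "b", "c", "d", "e"), 2),
                  subgroup = rep(c("flat", "hand"), each = 5),
                  n = 10L, events = 5L,
                  rate = c(rep(0.4, 5), c(0.1, 0.3, 0.2, 0.5, 0.4)),
                  stringsAsFactors = FALSE)
  s <- summarize_matrix(r)
  flat <- s[s$subgroup == "flat", ]
  expect_equal(flat$q75 - flat$q25, 0)
  hand <- s[s$subgroup == "hand", ]
  expect_equal(hand$median, 0.3)
  expect_equal(hand$q25, 0.2)
  expect_equal(hand$q75, 0.4)
  expect_equal(hand$min, 0.1)
  expect_equal(hand$max, 0.5)

  r$rate[r$subgroup == "flat"] <- NA
  s2 <- summarize_matrix(r)
  expect_identical(s2$n_hospitals[s2$subgroup == "flat"], 0L)
  expect_true(is.na(s2$median[s2$subgroup == "flat"]))
})
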