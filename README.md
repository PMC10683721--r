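# thrombovar

Explainable machine-learning analysis of why emergency stroke hospitals
differ in their use of thrombolysis.

Thrombolysis (clot-dissolving treatment for ischaemic stroke) is
strongly time-dependent, yet national stroke audits report several-fold
differences between hospitals in the fraction of eligible patients
treated. Is that the patients, or the hospitals? `thrombovar` answers
the question on synthetic stroke-audit data with a known ground truth,
for methodologists and audit analysts who want the machinery without
access to a registry:

* **Synthetic audit generator** — patient tables with the ten canonical
  decision features and labels drawn from an additive logistic model
  $\operatorname{logit} p = \beta_0 + \sum_k f_k(x_k) + \delta_{h}$,
  with piecewise-linear log-odds effects $f_k$ (e.g. odds falling 9-fold
  over the first 120 min of arrival-to-scan time) and per-hospital
  propensity offsets $\delta_h$ spanning an exact 13-fold odds ratio.
  Haemorrhagic stroke is never thrombolysed, deterministically.
* **Boosted-tree decision models** (`xgboost`) in k-fold, all-data and
  held-out-cohort variants, with one-hot hospital encoding so any
  patient can be counterfactually reassigned to any hospital.
* **SHAP decomposition in log-odds** — per-patient values, main effects
  and pairwise interactions (hospital block aggregated to one
  pseudo-feature), verified against a brute-force
  coalition-enumeration Shapley oracle; waterfalls; binned
  feature-effect summaries and fold-change estimators.
* **Subset SHAP** — each feature's main effect plus its interactions
  with same-subset features only, splitting every prediction into
  patient-descriptive and hospital-descriptive components.
* **Hospital variation analyses** — mean hospital SHAP main effect
  (propensity), the identical-cohort counterfactual (one fixed cohort
  predicted at every hospital), process correlates, a regression
  partition of between-hospital variance, and observed vs predicted
  thrombolysis rates for eleven clinical subgroups.

## Worked example

A small study: 8 hospitals, ~2,000 patients, everything driven by one
seed.

```r
library(thrombovar)

cfg <- generator_config(n_hospitals = 8, patients_per_hospital = 250, seed = 7)
ds  <- generate_dataset(cfg)

## how well is the decision predictable?
kf <- fit_kfold(ds$patients, model_config("kfold", seed = 7))
kf$metrics
#> accuracy 0.737 | ROC AUC 0.799 | sens=spec 0.710 @ 0.355
#> hospital-level r2 0.995 | MAE 0.88 percentage points

## feature effects in odds, recovered from SHAP values
fit  <- fit_all_data(ds$patients, model_config("all_data", seed = 7))
shap <- compute_shap(fit, ds$patients)
fold_change_span(ds$patients, shap, "arrival_to_scan", from = 0, to = 120)
#> [1] 9.5      # generator truth: 9-fold over the first 120 min

## hospital propensity: SHAP main effect vs the generator's true offsets
tensor <- compute_interactions(fit, ds$patients)
eff <- mean_hospital_main_effect(tensor, ds$patients, ds$hospitals)
cor(eff$mean_main_effect, eff$true_offset, method = "spearman")
#> [1] 1

## the identical cohort sent to every hospital
hold <- fit_holdout(ds$patients, model_config("holdout", holdout_size = 400, seed = 7))
cf <- counterfactual_cohort(hold$model, hold$cohort, hold$holdout_idx)
round(100 * range(cf$predicted_rate), 1)
#> [1] 14.0 45.3   # same patients, 14% at one hospital, 45% at another

## how much between-hospital variance does each component explain?
att <- subset_shap(tensor, default_subset_assignment())
regress_partition(per_hospital_subset_means(att, ds$patients))
#> between-hospital variance explained (r-squared):
#>   patient   0.089 (p = 0.47)
#>   hospital  0.964 (p = 1.5e-05)
#>   combined  0.993 (p = 3.4e-06)
```

The per-hospital cross-validated predictions track observed use almost
perfectly (r² 0.995), the 9-fold arrival-to-scan effect is recovered as
9.5-fold, hospitals are ranked exactly by their true propensity, and —
because this generator makes hospitals, not case mix, the dominant
source of variation — the hospital-descriptive component explains ~96%
of the between-hospital variance while the patient mix explains ~9%.

Per-patient explanations come from `waterfall()`:

```r
w <- waterfall(shap$values[1, ], shap$base[1])
head(w[, c("feature", "contribution", "cumulative_probability")], 4)
#>           feature contribution cumulative_probability
#> 1 arrival_to_scan       -0.591                  0.220
#> 2           nihss       -0.436                  0.154
#> 3   anticoagulant        0.239                  0.188
#> 4       prior_mrs        0.204                  0.221
```

`run_all(run_config(seed = 7), "out/")` runs every stage in order and
writes per-stage CSV/JSON plus a checksummed manifest; `report_run()`
summarises it.

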