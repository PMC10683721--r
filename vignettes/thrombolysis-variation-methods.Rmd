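---
title: "Methods: explainable analysis of between-hospital thrombolysis variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: explainable analysis of between-hospital thrombolysis variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Thrombolysis is a time-critical, clot-dissolving treatment for acute
ischaemic stroke. National stroke audits show that the fraction of
eligible patients (those arriving within 4 hours of a known or estimated
onset) who actually receive it varies several-fold between emergency
stroke hospitals. Two explanations compete: hospitals see different
patients (case mix), or hospitals make different decisions for the same
patient (propensity and process). `thrombovar` implements an
explainable-machine-learning pipeline that separates the two.

Because national audit registries are not freely redistributable, the
package is built around a synthetic stroke-audit generator with a fully
known ground truth. Every downstream claim — attribution, counterfactual,
variance share — can therefore be checked against the quantity it is
supposed to recover, which is exactly what the test suite does.

## The synthetic audit generator

One row per patient with the ten features routinely found to drive the
decision: arrival-to-scan time, stroke type (infarction vs haemorrhage),
stroke severity (NIHSS, 0–42), precise vs estimated onset time,
pre-stroke disability (mRS, 0–5), stroke team attended, anticoagulant
use, onset-to-arrival time (capped at 240 min, the audit's 4 h window),
onset during sleep, and age as the midpoint of 5-year bands
(37.5–92.5).

Labels are drawn from an additive logistic decision model:

$$
\log \frac{p}{1-p} \;=\; \beta_0 \;+\; \sum_k f_k(x_k) \;+\; \delta_{h(i)},
$$

with piecewise-linear effects $f_k$ in log-odds whose spans default to
the fold-changes reported for the England-and-Wales audit: odds falling
9-fold over the first 120 min of arrival-to-scan time (and a further
2-fold to 240 min), rising 30-fold from NIHSS 0 to a plateau at 15–25
and falling 5-fold towards 42, falling 3-fold for estimated onset time,
6-fold from mRS 0 to 5, 5-fold under anticoagulation, 3-fold between 120
and 240 min onset-to-arrival, 2-fold per 30 years beyond age 80, and
4-fold for onset during sleep. Haemorrhagic stroke is not modelled as a
large negative coefficient: its label is a deterministic 0, because real
practice forbids thrombolysing a bleed. The generator consequently never
emits a thrombolysed haemorrhage, and `true_log_odds()` refuses
haemorrhage records outright.

Hospital propensity offsets $\delta_h$ are drawn normal and then
affinely rescaled so the extreme odds ratio between hospitals is
*exactly* the configured `hospital_offset_span_fold` (default 13).
Hospitals also differ in process: median scan-to-needle time is
negatively coupled to the offset (default 6 min per log-odds unit, noise
SD 8 min), and each hospital shifts the arrival-to-scan distribution by
a location term (SD 5 min). Team sizes are proportional to log-normal
annual admissions.

Feature marginals are independent by design, with one exception: age and
pre-stroke mRS share a latent Gaussian copula whose correlation (0.47)
was calibrated once so the realised r² between the two features is about
0.146, the value reported for the real registry. The registry also shows
a weaker dependence between sleep onset and estimated onset time (r²
0.078) which the generator deliberately does not emulate — a documented
simplification. Other marginals (log-normal arrival-to-scan with median
32 min, truncated log-normal onset-to-arrival with median 95 min, gamma
NIHSS, 12% haemorrhage, 70% precise onset, 12% anticoagulated, 8% sleep
onset, discretised-normal age peaking in the late 70s) were chosen once
as plausible for a 4-hour-arrival stroke cohort; they are not
registry-calibrated, so tests passing on synthetic data demonstrate that
the *methods* recover a known truth, not that the generator reproduces
the registry.

The intercept (−0.3) puts the overall thrombolysis rate near 35% of
4-hour arrivals, inside the plausible audit range, and makes the
"ideal" subgroup (see below) receive thrombolysis at a ~90% median
hospital rate. All randomness flows from a single master seed through
per-stage substreams, so a config reproduces its dataset byte for byte.

The default study size is 30 hospitals × 700 patients on average
(~21,000 rows) — about the per-hospital volume of the real three-year
audit, at a hospital count that keeps a full interaction decomposition
affordable on one CPU. Experiments that repeat a condition across seeds
(fold-change recovery, null variance partition, decoy selection) use
five seeds at this scale.

## Models

`xgboost` gradient-boosted trees predict the thrombolysis decision from
the nine numeric features plus a one-hot indicator block for the stroke
team — one column per team, so a patient can be "moved" to another
hospital by rewriting the block. Three variants mirror common usage: a
label-stratified k-fold model (accuracy surface, feature selection), an
all-data model (attribution analyses), and a holdout model trained on
all but a label-stratified held-out cohort (counterfactual analyses,
which require cohort–training disjointness; the package raises a
leakage error otherwise).

Defaults are depth 3, 150 rounds, learning rate 0.3, no subsampling,
single-threaded. The decision model being recovered is additive in
log-odds, so shallow trees cost nothing in accuracy; the round count was
chosen for *fidelity*: with too few rounds the fitted margins are
visibly shrunk towards zero (e.g. a true 4-fold sleep effect recovered
as ~3.1-fold at 50 rounds but ~3.8-fold at 150), which biases every
fold-change estimate downward. Depth is kept low because the pairwise
SHAP interaction pass scales with both tree size and the number of
encoded columns; at these defaults a full 21,000 × 39-column
interaction tensor takes about two minutes on one CPU. The accuracy
threshold is 0.5; the equal-sensitivity/specificity point is found by
linear interpolation between adjacent score thresholds.

## Attribution

SHAP values are computed by path-dependent TreeSHAP (training data as
background, via `xgboost`'s native implementation), expressed in
log-odds so they are additive: base value + contributions = raw margin,
asserted for every row at 1e−3 (the library returns single-precision
values; observed error is ~1e−6). The interaction tensor stores, per
patient, a symmetric feature×feature matrix: main effects on the
diagonal and *half* of each pairwise interaction on the two symmetric
off-diagonal entries, so row sums recover total SHAP values. The one-hot
team block is aggregated by summation on every axis into a single
"hospital attended" pseudo-feature; its main effect includes the
within-block terms.

The path-dependent expectation convention (rather than interventional)
keeps the base value equal to the expected training margin — the
familiar "base rate" of a waterfall plot. Waterfalls order features by
absolute contribution and report cumulative partial sums through the
logistic, ending exactly at the predicted probability.

**The oracle.** `exact_shapley_oracle()` recomputes Shapley values by
enumerating all $2^M$ coalitions, with the coalition value defined by
recursive tree descent over a background table (absent features average
the children weighted by background row counts) and pairwise interaction
values by the discrete second difference. Two numerical details matter.
xgboost stores feature values in single precision, so the oracle rounds
to float32 before comparing against split thresholds; and fixture
ensembles are trained with `tree_method = "exact"` and squared-error
loss, because the default histogram method can assign boundary rows to a
different side during training than at prediction time, and non-unit
hessians would make stored node covers diverge from background row
counts. Under those fixture conditions the fast path and the oracle
agree to ~2e−7, comfortably within the 1e−6 contract.

**Subset SHAP.** Given a partition of features into named subsets, a
feature's subset SHAP value is its main effect plus its interactions
with same-subset features only — the restricted row sum of the
symmetric tensor. Two reductions pin the convention: the all-in-one
partition returns each feature's total SHAP value, and the
all-singletons partition returns the main effects, both exactly. (A
formulation that added both symmetric halves per pair would break the
first reduction, which is why the restricted row sum is the one
implemented.)

**Fold changes.** `shap_vs_value_summary()` bins a feature and reports
median and quartile SHAP per bin; `fold_change()` exponentiates a
difference of bin medians. For a continuous feature with a known span
the package also provides `fold_change_span()`, which fits the binned
medians against binned feature medians by least squares and evaluates
the fitted line at the span endpoints. The plain bin-median contrast
systematically understates an effect span — the outer bins' medians sit
well inside the endpoints, sparse tail bins are noisy, and chance
correlation between a hospital's arrival-to-scan shift and its
propensity offset lets path-dependent SHAP share credit with the team
feature — so the span estimator is the one used to compare against the
generator's ground-truth spans.

## Hospital variation

A hospital's *propensity* is its mean SHAP main effect of the hospital
attended, computed over its own patients. The counterfactual analysis
sends the identical held-out cohort to every hospital by rewriting the
indicator block and averages predicted probabilities — case mix held
exactly fixed, so remaining differences are the hospital's. The
per-hospital main effect on the counterfactual rows is computed on a
fixed leading subset of the cohort (default 250 rows, identical across
hospitals, as interaction tensors are the expensive step); means remain
comparable because the rows are the same. Process descriptors
(admissions, scan-to-needle speed) are related to propensity by per-descriptor
ordinary least squares with raw two-sided p-values.

## Variance partition

Features are split into patient-descriptive (age, severity, prior
disability, onset-to-arrival, stroke type, onset-time type,
anticoagulants, sleep onset) and hospital-descriptive (arrival-to-scan
time, hospital attended) subsets; arrival-to-scan is classed as a
hospital process, though the assignment is configurable since scan
priority can reflect clinical presentation. Per hospital, the mean
summed subset SHAP value of its patients is regressed (OLS, one point
per hospital, unweighted, rates in percent) against the observed
thrombolysis rate: patient-only, hospital-only, and combined. The
combined fit nests the single fits, so its r² bounds both.

One pitfall is handled explicitly. If hospital identity carries no real
signal, a converged boosted model still absorbs each team's in-sample
label noise into its indicator block, and that same noise defines the
team's observed rate — so the hospital-only r² would stay high (0.5–0.7
in measured null runs) no matter the scale. The package therefore gates
hospital identity on its pooled out-of-fold AUC gain (threshold 0.001,
the same equivalence margin used in feature selection) before giving it
attribution: `variance_partition_analysis()` drops the team block from
the model when the gain is below threshold. Under default conditions
the gain is ~0.05 and the gate never binds; under a no-hospital-effect
null it reliably excludes the block and the hospital share collapses to
the noise floor.

## Feature selection and subgroups

Greedy forward selection adds, each round, the candidate that maximises
k-fold ROC AUC (mean of fold AUCs by default, pooled out-of-fold
optionally; ties broken lexicographically), stopping when within
`epsilon = 0.001` of the all-candidate model. The team block enters as a
single candidate. A structural caveat found during validation: with age
bands capped at 92.5 the generator's age effect spans at most 1.33-fold
over ~26% of patients, an incremental AUC of order 1e−4 —
indistinguishable from the evaluation jitter that ten pure-noise decoys
produce at 21,000 rows. In repeated runs the other nine features are
always selected before any decoy; age is not reliably separable from
noise at this scale, and the test suite documents that honestly rather
than enlarging the effect.

Eleven clinical subgroups are built in: an "ideal" thrombolysis
candidate (infarction, scan < 30 min, NIHSS 10–25 inclusive, precise
onset, mRS 0, no anticoagulants, onset-to-arrival < 90 min, age < 80,
awake onset), nine single-feature sub-optimal groups, and NIHSS < 5
with estimated onset combined. Interval subgroups use half-open bins
(e.g. [60, 90) min) to avoid double counting; "age 80+" means band
midpoints of 80 and above. Observed rates are plain arithmetic per
hospital with a minimum cell count of 5 (configurable) before a rate is
reported; predicted rates reuse the counterfactual machinery per
subgroup.

## Orchestration and reproducibility

`run_all()` executes generate → train → (optionally select) → explain →
hospital analysis → variance → subgroups from one `run_config()`,
writing CSV/JSON per stage plus a manifest with MD5 checksums; the same
config reproduces identical checksums. The exported functions are the
interface — the pipeline is an R API, not a shell tool.
`scripts/acceptance.R` re-runs the whole analysis from scratch at the
default study scale and writes every headline quantity it computes as
JSON.

## Limitations

Synthetic data demonstrate method correctness, not registry fidelity:
marginals are plausible rather than calibrated, feature dependences
beyond age–disability are absent, the decision model is additive (no
hospital-specific tolerances by default), and there is no missing data.
Results are associational — hospital propensity as measured here is not
a causal effect of any named process — and the analysis does not
address variation between clinicians within a hospital.
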