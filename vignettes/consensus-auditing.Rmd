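---
title: "Auditing mortality classifiers with repeated-resampling decision fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing mortality classifiers with repeated-resampling decision fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What the audit measures

A mortality classifier with an AUROC of 0.9 still disagrees with itself: a
patient predicted to die under one train/test split may be predicted to
survive under another, and different model families routinely disagree on
the same patient even when their population metrics are indistinguishable.
`icuconsensus` quantifies this by repeating the complete
split/train/threshold/predict cycle many times with four voters — ridge
logistic regression, gradient-boosted trees, adaptive boosting of decision
stumps, and a fixed clinical reference probability — and fusing all binary
votes per patient. Patients whose votes agree at least `threshold`% of the
time get a final Alive or Dead prediction and, crossed with their actual
discharge status, land in TN, FN, TP or FP; everyone else is MIXED. The
MIXED group is the audit's deliverable: patients for whom the available
features, under any of the fitted models, do not support a stable decision.

## The consensus procedure and its conventions

Several small conventions are fixed here because the underlying procedure is
ambiguous about them. They are all switchable or at least explicit:

* **Stratified splits.** Each round draws 25% of each outcome class into the
  test set (`test_fraction = 0.25`), so both partitions match the cohort
  death rate to within one patient. Round `r` uses seed `base_seed + r`;
  rounds share no other state.
* **Youden threshold on the training predictions.** Each voter's decision
  threshold maximizes `J = sensitivity + specificity − 1` over the distinct
  observed scores; exact ties resolve to the smallest threshold (the
  comparison is done in integer arithmetic, so ties are real ties). Fitting
  `J` on the training partition avoids letting test labels pick the
  threshold; `threshold_source = "test"` is available for the literal
  test-derived reading.
* **Score exactly at the threshold votes Dead.** An arbitrary but fixed
  boundary convention.
* **Agreement comparison is inclusive (`>=`).** A strict comparison would
  make the 100% threshold unattainable ("more than 100% of votes"), emptying
  the right edge of any threshold sweep; with `>=`, 100% means "all votes
  agree". `strict = TRUE` restores the strict reading. Thresholds live in
  (50, 100] so at most one class can win.
* **Grid-search ties take the first grid entry in declaration order**, and
  cross-validation is stratified with 5 folds by default (the fast fixture
  configurations use 3; see below).
* **The reference voter is thresholded per round like the learners**, but
  its continuous score is a stored column and never refits, so its
  prediction for a patient is identical across rounds up to threshold
  jitter.
* **Patients never drawn into a test set** are reported as unassessed rather
  than silently grouped. At 100 rounds the per-patient appearance count is
  Binomial(100, 0.25) — mean 25 — and the probability of zero appearances is
  negligible; short audits (few rounds) do produce unassessed patients.

## The synthetic cohort

Real eICU-style data requires credentialed access, so the package generates
cohorts with known ground truth. One latent severity variable `s` drives
everything:

* **Subgroups.** Each patient belongs to `clear_alive` (67.4%,
  `s ~ N(−4, 1)`), `clear_dead` (10.6%, `s ~ N(3, 1)`) or `ambiguous`
  (22%, `s ~ N(0, 0.1)`). Mortality risk is `plogis(a + 1.5 s)`, with the
  intercept `a` solved numerically so the marginal death rate equals the
  configured prevalence (default 0.105). The outcome is a Bernoulli draw
  from that risk.
* **Worst-value features.** ICU feature tables record the measurement in the
  first 24 h furthest from a clinical reference value, which makes vital
  signs bimodal (a too-low peak and a too-high peak). `sample_worst_value()`
  reproduces this with a two-component Gaussian mixture; the weight on the
  mode further from the reference is `plogis(s × severity_loading)`, so
  draws are evenly bimodal for mid-severity patients and drift to the
  extreme peak as severity rises. Blood urea nitrogen carries the largest
  loading (2.6) and is the planted "most informative" feature that the
  attribution chain is expected to surface.
* **Informative missingness.** Each feature is masked at its schema
  `missing_rate`, tilted on the log-odds scale by `−strength × s` (centred,
  so the marginal rate stays at the schema rate). Sicker patients therefore
  have fewer missing values — they get tested more — and FiO2 keeps its
  characteristic ~73% missingness.
* **Auxiliary columns.** APS is log-linear in severity
  (`exp(3 + 0.55 s + noise)`, median ≈ 20, right-skewed like a real acute
  physiology score); ICU length of stay is lognormal with a mild severity
  slope; the hospital discharge offset equals the unit offset (the patient
  leaves the hospital, or dies, straight from the ICU) with probability
  `plogis(−1.9 + 0.9 s)`, and otherwise adds an exponential tail.
  Anthropometric artefacts (heights and weights far outside human ranges)
  are planted at a 0.4% rate for the imputation stage to catch.

### Why the ambiguous subgroup is built the way it is

The design goal is that ambiguous patients end up MIXED because the *data*
cannot decide them, not because of a lucky seed. Two facts shaped the
construction, both established empirically while designing the generator:

1. With Youden thresholding, every voter places its cut on the **same side**
   of a coherent mid-range cluster. Where the cut lands is decided by the
   sign of `p_amb − prevalence` (the cluster's event rate versus the
   marginal death rate) at the *cohort* level, so re-splitting the same
   cohort a hundred times never flips it. Vote splits cannot come from round
   noise alone — a design relying on a "flat" Youden objective recovers only
   about half of the planted ambiguity.
2. What does produce stable splits is **structural disagreement between
   voters**. The generator therefore anchors two voters on opposite sides:
   the ambiguous event rate is set slightly below prevalence
   (`p_amb ≈ 0.08` versus 0.105), which makes all three learners vote Alive
   on the cluster decisively (the margin is several standard errors of the
   per-round noise); and the reference probability carries a mid-severity
   over-prediction bump (`reference_miscalibration`, amplitude 4.2 logits,
   width 0.8), which pushes its scores for ambiguous patients into the
   clearly-dead score range. Unable to separate the two, the reference's
   Youden cut settles below both, and the reference votes Dead on every
   ambiguous patient. Each ambiguous patient then carries a permanent
   ~75%/25% vote split — MIXED at the 90% threshold — while clear patients
   get unanimous votes.

The miscalibrated reference is not a trick: transported legacy severity
scores (APACHE among them) are well documented to keep their discrimination
but lose calibration on new cohorts, typically over-predicting mortality in
the intermediate-risk band. The generator reproduces exactly that failure
mode; set `reference_miscalibration = c(amplitude = 0, width = 0.8)` for a
perfectly calibrated reference, at the cost of the planted ambiguity no
longer being recoverable as MIXED.

The severity spread of the ambiguous group (sd 0.1) keeps the outcome
essentially independent of the features within the group — a logistic model
restricted to ambiguous patients performs near chance (the test suite
asserts AUROC < 0.65) while separating the clear subgroups almost perfectly
(> 0.9).

## Feature attributions

Additive per-prediction attributions use the exact backend natural to each
family: xgboost's built-in tree-path attributions (TreeSHAP, log-odds
scale); the closed-form linear decomposition `β_j (x_j − mean_j)` for the
ridge logistic model (link scale, training means recorded at fit time); and
per-stump attributions for the boosted stumps, which are exact because each
depth-1 stump depends on a single feature (probability scale). The reference
voter has no features and is excluded. In every case the base value plus the
row sum reproduces the model output, and the tests assert that contract.

The aggregation chain is: take absolute values and normalize each prediction
row to sum to 1 (the direction of effect is deliberately discarded — the
tables report how much a feature matters, not which way it pushes); merge
one-hot indicator columns into their parent categorical feature; average
rows within each patient; average patients within each consensus group. The
merge happens *before* the patient-level mean so the ALL table and the
per-group tables come from one pipeline order. Totals of 1 are conserved
through the whole chain, which the tests check to 1e-6.

## Distribution comparison

`kde_by_group()` uses Gaussian kernels with Silverman-type bandwidths
(`stats::bw.nrd0`) per group, evaluated on a shared 512-point grid spanning
the pooled data range ± 3 maximal bandwidths. Display cutoffs (default
20 000 minutes for the discharge offsets, about two weeks) exclude extreme
values from estimation but always report how many were excluded. All
comparisons run on the raw, un-imputed values: imputed cells would pile mass
on the training mean and misrepresent the patients. No formal two-sample
tests are attached — the comparison is descriptive, and the package
deliberately stops there.

## Problem sizes and numerical choices

The shipped test suite and the acceptance script audit a cohort of about
5 000 selected patients (8 250 generated; the age/length-of-stay/single-stay
filters remove roughly a third) over 20 rounds with single-configuration
grids (ridge λ = 0.1; depth-3, η = 0.3, 40-round boosted trees; 40 boosting
stumps) and 3-fold CV — sizes chosen so a full audit completes in a couple
of minutes while keeping every per-group statistic stable across seeds. The
occurrence statistics use the full 100 rounds with model fitting stubbed
out, since appearance counts depend only on the split schedule. Production
audits would use `default_model_specs("default")` (small exhaustive grids,
5-fold CV) and 100 rounds.

Degenerate inputs are handled explicitly: single-class partitions abort with
the round and family named; a feature entirely missing in training is a
named error; all-zero attribution rows fall back to the uniform split and
are counted; KDE groups below two observations are omitted with a message;
zero-appearance patients are never fused.

## Limitations

The generator emulates marginal structure, not clinical reality: features
are conditionally independent given one severity dimension, there are no
time series (only the 24-h worst-value summary), no multi-site effects, no
correlated comorbidity patterns, and the reference score's failure mode is
a single smooth miscalibration. Passing the synthetic tests therefore shows
that the pipeline's mechanics are correct — splits stratify, imputation
does not leak, thresholds optimize what they claim, fusion partitions,
attributions conserve mass, planted structure is recovered — not that any
particular clinical dataset will show the same group sizes or feature
rankings. Mean imputation and hard Youden thresholds are faithful to the
audited procedure but are themselves known simplifications; model-based
imputation and calibrated, threshold-free fusion are natural extensions and
deliberately out of scope.
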