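---
title: "Methods: directional attribution modelling of radiation-induced lymphopenia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: directional attribution modelling of radiation-induced lymphopenia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rilshap` analyses radiation-induced lymphopenia (RIL) — the decline of
circulating lymphocyte counts after radiotherapy — as a binary event in a
tabular patient cohort. This vignette documents the statistical procedure,
the assumptions behind each stage, the tunable parameters, the numerical
choices, and what the synthetic data generator can and cannot establish.

## Outcome definition

The event is CTCAE v4.0 lymphopenia grade ≥ 1: a post-radiotherapy lymphocyte
count below the lower limit of normal (LLN). `grade_lymphopenia()` applies
the cutpoints — grade 0 at or above the LLN, then 800, 500 and 200 cells/µL
closed below — and the binary outcome is grade ≥ 1. The LLN defaults to
1000/µL (1.0×10⁹/L); laboratories differ, so it is configurable, and counts
reported in 10⁹/L must be converted (×1000) before grading. Grades 2–4 are
computed and exposed although the downstream models only use the binary
event.

## Feature handling

Features fall into five groups: clinical, tumour characteristics, baseline
blood counts, radiotherapy dosimetrics, and treatment regimens.
`encode_cohort()` builds the design matrix with k−1 dummy indicators per
categorical feature (the reference level, the first listed, is never
emitted) and passes continuous features through unscaled. Missing values are
preserved: the tree learner consumes them natively on its default branch, so
all rows are used; the penalised regression is restricted to complete-case
rows. Continuous features are deliberately *not* standardised for the tree
models (trees are invariant to monotone transformations) and are
standardised only inside the penalised fitter (penalty fairness).

## Univariate screen

One logistic regression per feature: odds ratios with Wald 95% intervals on
the log scale, and for a single binary contrast the MLE equals the 2×2
cross-product ratio ad/bc — which is how the screen is validated against
printed contingency tables. Bonferroni adjustment uses m = the number of
odds-ratio rows actually computed in the run, recorded in the output; the
screen makes no attempt to guess the m used by any external publication.
Separation (a zero cell) is flagged and the unstable estimate reported as
fitted, rather than silently corrected by penalisation — degenerate rows in
published tables look exactly like this.

## Resampling engine

`make_plans()` fixes the resampling design: per iteration an 80% draw of
patients, a 7:3 train/test split, and a 10-fold assignment on the training
set. Three design points the procedure's conventional description leaves
open are resolved as follows:

* the 80% draw is **without replacement** (a with-replacement option
  exists); the draw is conventionally called "bootstrapping" but an 80%
  subsample is what the stated fraction implies;
* the train/test split and the folds are **stratified by outcome**, which
  avoids degenerate single-class test sets at moderate n;
* hyperparameters are re-tuned **per iteration** when a grid is supplied;
  a shared-tuning workflow is a one-line change (tune once, pass `params`).

The tree classifier's search grid is: learning rate 0.01–0.1 (step 0.01),
gamma 0–5, max depth 3–6, positive-class weight 1–2 (step 0.2), row and
column subsampling 0.7–1 (step 0.1), minimum child weight 3–6, maximum delta
step 0–5 — 552,960 configurations. The default search is randomized over 200
configurations with a tuned fast-path configuration (learning rate 0.04,
gamma 5, depth 3, class weight 1.8, subsample 0.8, column subsample 0.7,
child weight 5, delta step 1) always included; an exhaustive mode exists but
is not a desk-scale computation. Ties on mean CV ROC-AUC break toward lower
depth, then lower learning rate, then first seen — preferring the simpler
model. The number of boosting rounds is fixed (default 200, configurable);
early stopping is not used. Folds whose training portion is single-class are
skipped with a log message; if all folds degenerate the tuner errors.

The penalised comparator is an L1 logistic regression fitted on complete
cases with the penalty chosen on the cross-validated ROC-AUC path. The
default takes the **one-standard-error** penalty (the largest penalty whose
CV AUC is within one SE of the maximum). The AUC-maximising penalty itself
(`rule = "min"`) is available, but under a pure-noise simulation it selects
each null feature roughly half the time — the one-SE rule keeps the null
selection frequency low (median one of fifteen noise features) and produces
the heavily sparse coefficient profiles that make the tree-vs-lasso
comparison informative.

Evaluation reports sensitivity, specificity, accuracy and F1 at a fixed
classification threshold of 0.5 (probability scale; configurable — the
procedure this package operationalises does not state one), ROC-AUC by the
trapezoidal rule over the empirical curve, and PR-AUC by step interpolation.
Single-class evaluation sets yield missing AUCs, not errors.

## Directional attribution

Per-instance attributions are exact tree-path (TreeSHAP) values on the
log-odds margin, where additivity is exact: base value plus the row sum
equals the raw score to float precision (asserted at 1e-4). Attributions are
computed on each iteration's **test** split: attributing memorised training
noise would inflate spurious importance. Importance is mean |SHAP| within
iteration, then across iterations.

The direction score is, per feature, the mean over iterations of the
Spearman rank correlation (average ranks on ties) between the feature's
attribution column and a correlate; iterations where the column is constant
contribute 0, keeping the mean well defined. The package defaults to
correlating with the **feature's own values**. The alternative — correlating
with the binary outcomes — is implemented (`mode = "outcome"`) but cannot
express protection: a feature's attribution column is a monotone component
of the model's prediction, so its correlation with the outcome is
non-negative for any feature the model actually uses, regardless of whether
the feature raises or lowers risk. Only the feature-value correlate
reproduces the defining behaviour of the score — ≈ −1 for a strongly
protective baseline lymphocyte count, ≈ +1 for a promoting dose metric —
and it is what the planted-effect recovery tests exercise.

The direction statistic is *sign-like*: the rank correlation saturates
toward ±1 whenever the model uses a feature at all, so its magnitude is not
an effect size. Under a global null the distribution of direction scores
across features is centred at zero, but any individual null feature can show
a large direction in a single cohort (the model monotonically fits that
cohort's spurious association); conclusions about single features should
rest on mean |SHAP| magnitude plus direction sign, never on direction
magnitude alone.

## Dose–volume analysis

Each dosimetric metric contributes one point: its representative irradiation
dose (Gy) and irradiated volume from DVH summaries. With importance `s` the
two regressions are OLS of `log10(volume) ~ s` and `log2(dose) ~ s`. The
choice of one point per metric (rather than per-patient clouds) reflects the
metric-level question — *which kind of dose exposure matters* — and the
cohort-representative value is the configured catalog value (a median-type
summary; a mean variant only changes the catalog input). Volumes with mixed
units (percent organ volume vs litres of body volume) are used as given
after the log transform, with a warning — the regression then pools
heterogeneous scales and its intercept is not interpretable. The per-metric
Pearson correlation of volume with dose across patients flags "heart-like"
metrics (negative link: in tangential breast plans a high mean heart dose
accompanies a *small* irradiated range); those are the metrics for which a
monotone volume–dose reading is invalid and which the reporting layer
excludes from monotonicity statements. The report restates only computed
quantities — slopes, standard errors, p-values, correlation signs — and no
biological claim.

## Matched-pair validation

To probe a feature masked by more important correlated ones, the discrepancy
between patients a and b over the important features (those with strictly
greater mean |SHAP| than the probe — the probe is never in its own
importance set) is the mean of |f_a − f_b| / f_max, with f_max the feature's
maximum over the analysis cohort, recomputed per cohort. Encoded categorical
indicators participate with f_max = 1. Pairs must have discordant outcomes
and discrepancy strictly below the threshold (default 0.10 — the procedure
this package operationalises does not state its threshold; at 0.10 a typical
synthetic cohort yields on the order of a hundred pairs). Selection is
greedy in ascending discrepancy with deterministic identifier tie-breaks and
no patient reuse — optimal (network-flow) matching is out of scope. The
probe is then tested with a two-sided paired t-test of (value in the event
member − value in the non-event member); zero-variance differences are
reported as degenerate rather than as a p-value.

## Synthetic cohort generator

The generator is first-class, tested code: it defines the conditions under
which every property of the pipeline is demonstrated.

What it emulates: a 589-patient cohort with a 57.7% event rate; nine
dosimetric features that are lognormal monotone functions of one latent
"irradiation extent" (log-loading 0.4, log-noise 0.3 — implying pairwise
correlations ≈ 0.6, comfortably above the 0.18 floor the multicollinearity
analysis assumes), each with a per-patient irradiated volume tied to the
extent with a configurable sign and exactly one heart-dose metric with a
negative link; six lognormal baseline blood analytes moment-matched to
published medians and quartiles; categorical features drawn from realistic
marginal proportions with the conventional reference levels; and a binary
outcome from a logistic model on standardised features with a configurable
signed effect vector. The default plants a strongly protective baseline
lymphocyte count (−1.2 log-odds per SD), a promoting integral body dose
(+1.0), a promoting bilateral-lung low-dose bath (+0.6) and a protective
platelet count (−0.5), leaving everything else null. The intercept is
calibrated to the target event rate by bisection on the mean logistic
response (tolerance 1e-4 — deterministic and derivative-free); the realised
rate then carries binomial noise (sd ≈ 2 percentage points at n = 589).
Post-radiotherapy lymphocyte counts are drawn from a truncated lognormal so
that CTCAE grading of the count reproduces the drawn outcome exactly.
Missingness is injected completely at random on continuous features only
(default 2%).

What it does not emulate: dependencies among categorical features, a joint
distribution between blood counts and dose metrics, informative missingness,
longitudinal blood-count trajectories, or fractionation schedules. Passing
tests on this generator therefore demonstrate that the *machinery* is
correct under the stated structure — not that real cohorts satisfy that
structure, and not the headline predictive performance of any real cohort,
whose data are not public.

## Problem sizes

The test suite demonstrates properties at sizes chosen to make each
statistical check informative while keeping a full run in tens of seconds:
planted-sign recovery uses 10 replicate cohorts of n = 589 with B = 20
iterations at the fast-path configuration; the paired-t null calibration
uses 10,000 Monte-Carlo replicates of 30 pairs; oracle-equivalence checks
use 1,000 random 2×2 tables; pipeline determinism is asserted byte-for-byte
on two B = 3 runs at n = 200. The engine itself defaults to the full-scale
design (B = 100, randomized search over 200 configurations).

## Known limitations

* The direction score's magnitude saturates (see above); it orders features
  reliably only jointly with mean |SHAP|.
* The outcome-correlate direction mode is measurement of predictiveness, not
  direction, and is retained only for comparison.
* Bonferroni correction with run-derived m is conservative and depends on
  how many contrasts a schema induces.
* Greedy matching is order-dependent under ties beyond the identifier
  tie-break and is not guaranteed maximum-cardinality.
* The univariate screen's Wald intervals are unreliable under separation;
  such rows are flagged, not fixed.
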