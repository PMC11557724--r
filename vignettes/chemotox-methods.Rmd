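---
title: "Methods: toxicity risk stratification, fairness auditing and data shift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: toxicity risk stratification, fairness auditing and data shift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`chemotox` implements a complete analysis pipeline for machine-learning
risk stratification of chemotherapy-induced renal and hepatic dysfunction:
multi-site cohort simulation, CTCAE-style outcome labelling, two-framing
predictive modelling with sensitivity-tuned decision thresholds, subgroup
and fairness evaluation, and cross-site data-shift reporting. This
vignette records the modelling assumptions, the parameters that matter,
and the design decisions taken where more than one reasonable choice
existed.

## The clinical problem and the outcome definition

Patients receive up to six chemotherapy cycles, each preceded by a blood
panel (creatinine and bilirubin in µmol/L, haemoglobin in g/L, absolute
neutrophil count in 10⁹/L, ALT in U/L), plus a pre-treatment baseline.
The outcome of interest is a *grade change toward toxicity*: the first
treatment cycle at which an analyte's CTCAE-style grade strictly exceeds
the lowest grade observed at any earlier cycle (baseline included).
Decreases in grade never count; a patient who worsens, recovers and
worsens again is counted once, at the first worsening. A consequence of
grading against the *best prior* grade is that a patient who starts at
grade 1, improves to 0 and returns to 1 does register an event — the
return is a deterioration relative to their best observed state.

The grade ladders are configurable; defaults are grade 1 above
`max(1.5 × baseline, 1.5 × ULN)` with higher rungs at 3× and 6× ULN for
creatinine, and 1.5× / 3× / 10× ULN for bilirubin. Default upper limits of
normal are 104 (male) / 90 (female) µmol/L for creatinine and 21 µmol/L
for bilirubin; all are parameters because laboratory reference ranges
vary. A value's grade is the highest rung it *strictly* exceeds, with
rungs made cumulative so grading stays monotone for patients whose
elevated baseline would otherwise place the grade-1 rung above the
grade-2 rung.

## Two prediction framings

Rather than classifying directly, the pipeline fits *regression* models
for the cycle-*n* analyte value (in natural units) and derives the risk
class afterwards. This keeps the classifier's operating point adjustable
without retraining. Two framings are supported (`framing_spec()`), for
targets *n* in 3–6:

* **fixed-early** — features are demographics plus the labs from cycles 1
  and 2, whatever the target cycle;
* **rolling** — features are demographics plus the labs from cycles
  *n−1* and *n−2*.

Each (patient, target cycle) pair is a separate sample, so a fully
observed patient contributes four rows. Since toxicity can first appear
at any cycle, only the rolling framing sees recent data for late targets;
the package's tests verify the expected consequence — that rolling
dominates fixed-early at cycle 6 when events are late-onset.

### Decision threshold

Predictions become classes via a deliberately conservative boundary
(`classify_risk()`): a prediction is high-risk when it reaches
`1.4 × baseline` *or* `1.4 × ULN` for creatinine (an effective threshold
of `min(1.4 × baseline, 1.4 × ULN)`, the OR maximising sensitivity) and
`1.4 × ULN` for bilirubin. The 1.4 multiplier is tighter than the 1.5×
grade-1 rung: lowering the multiplier can only flag more records, so
sensitivity is monotone non-increasing in it — the property
`threshold_sweep()` exposes and the tests check. The boundary is
inclusive (`≥`), fixed so the behaviour at exact multiples is
deterministic.

Two related choices deserve explicit statement:

* **Ground truth** for classifier evaluation is per patient-cycle record:
  whether the *observed* value at the target cycle is grade ≥ 1 under the
  1.5× ladder. The 1.4× multiplier applies only to model predictions;
  using the tuned threshold for ground truth as well is supported through
  the `ladder` argument but is not the default.
* The first-grade-change labels (`derive_labels()`) define per-patient
  outcome *prevalence* for cohort summaries; per-record evaluation uses
  the grade-at-cycle truth, which correctly scores a model that flags a
  patient whose dysfunction persists across several cycles.

## Model fitting

The learner is gradient-boosted regression trees (xgboost), behind a
fit/predict contract so it is replaceable. Around it the package owns:

* **Standardisation** — features are centred and scaled to unit variance
  with parameters estimated on training rows only; constant features are
  flagged and mapped to zero. Validation data never touch the transform's
  estimation.
* **Splitting** — patient-level, so a patient's rolling samples never
  straddle the train/test boundary; whole sites can be held out as
  external (unseen-site or temporal) validation.
* **Hyperparameter search** — a seeded random search over tree depth 2–8,
  learning rate 0.01–0.3 (log scale), 50–500 trees and subsample 0.5–1,
  scored by patient-grouped K-fold cross-validated RMSE and refit on all
  training rows. Random search is simple, reproducible under a single
  seed, and effective in low-dimensional spaces; the search strategy is
  deliberately pluggable behind `train_regressor()`'s contract. Ten folds
  and 50 trials are sensible analysis defaults; the package's own test
  and acceptance runs use 2–6 trials and 3–5 folds, which on the
  synthetic cohorts already separate signal from baseline decisively.
* **Categorical encoding** — one-hot, at the granularity of the active
  aggregation scheme (below), so the fine-versus-broad experiment changes
  *only* the encoding.

## Fairness measures

Each validation record receives a benefit `b = M(x) − y + 1` with
prediction and label in {0, 1}: false negatives get 0 (the highest
penalty — a missed high-risk patient), false positives 2, correct calls 1.
Inequality of the benefit distribution is the Generalised Entropy Index

\[ I^\alpha(b) = \frac{1}{n\alpha(\alpha-1)} \sum_{i=1}^n
   \left[\left(\frac{b_i}{\mu}\right)^\alpha - 1\right], \]

with the between-group form replacing each record by its group mean
(`between_group_gei()`). α = 2 is the default and the only form used in
reports. For α = 2 the decomposition
`I² = I²_between + Σ_g (n_g/n)(μ_g/μ)² I²(b_g)` holds and is verified to
1e-10 against naive-summation oracles. Numerical conventions: a mean
benefit of zero (an all-false-negative record set) raises a dedicated
degenerate-input error rather than returning infinity; threshold sweeps
drop such points with a message; between-group values are reported as the
formula yields them, without clamping, even where they are negative.
Default grouping dimensions are sex, broad ethnicity and age decade
(18–19-year-olds fall in the 10–19 band; 90+ is pooled), with groups
under 10 records omitted from subgroup *performance* tables — metric
estimates on fewer records are noise.

The 0/0 conventions for precision, recall and F-beta are all "return 0":
conservative and deterministic.

## The synthetic cohort generator

The generator is first-class, tested code — the study conditions for
everything downstream. Its default four site profiles emulate the
packaged per-site reference counts: cohort sizes 627, 144, 1280 and 1563;
age medians 55–64 with ranges from 18; sex mixes from 54% to 84% female;
site-specific tumour mixes over breast, bowel, DLBCL, lung and ovarian
(lung and ovarian only at the fourth, temporally shifted site, which
carries a 1.05 multiplicative drift on lab means); and per-analyte
grade-change rates of 4–17% computed as events / patients from the same
counts. Site-level additive shifts on mean baseline creatinine (0, +8,
−5, +3 µmol/L) give the shift-detection machinery a real signal.

Mechanics, chosen as the simplest that the labeller can verify:

* Baseline labs are truncated normal draws; creatinine and haemoglobin
  carry sex offsets.
* Trajectories are `baseline × lognormal AR(1)` noise (serial correlation
  0.6, log-SD 0.08, scaled per analyte), so within-patient values cohere
  across cycles.
* Injected toxicity events (per-analyte Bernoulli at the site rate, event
  cycle uniform over 3–6 by default) add a sustained step: from the event
  cycle onward the analyte is drawn around `2 × max(baseline, ULN)`
  (creatinine) or `2 × ULN` (bilirubin). Because the step multiplier must
  exceed 1.5, injected events clear the grade-1 rung with near
  certainty, and spontaneous noise essentially never does (it would need
  a 5-SD log excursion) — so the labeller recovers injected events
  one-for-one, which the tests assert at ≥ 95%.
* Panel missingness is applied after event injection, whole panels at a
  time, with a monotone per-cycle curve; the baseline panel is never
  blanked. Default profiles use zero missingness: they emulate
  complete-case analysis cohorts, with raw-extract missingness opt-in.
* An optional `regimen_risk` ties the event probability to one named
  regimen, the planted-signal construction behind the aggregation
  experiment.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: pharmacokinetics, dose reductions and delays,
correlations between comorbidities and toxicity risk, informative
missingness, inter-analyte correlation beyond shared patient noise, and
calendar-time effects richer than one multiplicative drift. Results on
synthetic cohorts validate the *machinery* (labelling, splits, metrics,
fairness algebra, shift statistics), not clinical performance.

## Subgroup aggregation experiment

`compare_fine_vs_broad()` trains two pipelines identical except for
categorical granularity: exact ethnicity codes and named regimens versus
broad ONS-style ethnicity groups (packaged 18 → 6 map) and regimen size
classes (singlet/doublet/triplet/quartet from drug counts; all packaged
breast regimens are doublets, so coarsening erases which breast doublet a
patient received). Both models are evaluated on the identical validation
records, and both subgroup reports are keyed on the records' original
demographics so they align row for row. When the generator ties risk to
one specific doublet, the fine model can isolate it and the broad model
cannot — the information-loss property the tests check directionally over
five seeds, with the affected tumour-type subgroup's F2 as the yardstick.

## Shift reporting

`compare_distributions()` compares *every* feature, not only
demographics, across every site pair: standardized mean difference
(pooled-SD denominator) and the two-sample Kolmogorov–Smirnov statistic
for numeric features, total variation distance for categorical ones, with
|SMD| or TVD above 0.1 flagged (the conventional negligible-imbalance
cut-off). Self-comparisons return exact zeros by construction.
`bias_audit()` assembles summary statistics, the shift table, per-site
holdout metrics, the formal fairness measures, deployment-restriction
flags (sites or groups whose F2 falls below a configurable floor) and the
aggregation-effect summary into one six-section JSON report.

## Cohort filter details

Inclusion: age ≥ 18, first-line treatment, at least two cycles, second
cycle no more than 60 days after the first — a gap of exactly 60 days is
retained; only strictly greater gaps exclude, the reading of "more than
60 days" fixed here and tested at the boundary. Exclusion reasons are
assigned in the fixed order age → first-line → one-cycle → gap →
missing-bloods, so each patient carries exactly one primary reason and
the log partitions the excluded set. Missing *blood* data at any of
cycles 0–6 excludes a patient; missing *demographics* never do — height,
weight and dose intensity stay `NA`, unknown ethnicity is an explicit
category, and uncollected comorbidity panels are all-`NA` rows.

Percentages in cohort summaries use the post-exclusion per-site patient
count as denominator, rounded to one decimal for sex and tumour mixes and
to the nearest integer for grade-change rates.

## Problem sizes and runtime choices

The test suite and the acceptance script size their simulations to
demonstrate each property at, but not beyond, the scale it needs:
marginal-recovery and missingness-rate checks at 2000–5000 patients
(binomial error a fraction of the asserted tolerance); the
signal-recovery experiment at 2000 patients with a 15% creatinine event
rate; directional experiments (rolling vs fixed-early, fine vs broad) at
800–1000 patients over five seeds with majority verdicts; the acceptance
pipeline on the full 3614-patient four-site cohort with 6 search trials
and 5 folds. All randomness flows from a single user-supplied seed.

## Known limitations

* The learner's conditional-mean predictions under-shoot rare extreme
  values, so very early targets (cycle 3 under the rolling framing, where
  both feature cycles predate any event) have little usable signal — as
  expected, and visible in the per-cycle tables.
* GEI depends on the validation set's composition; comparisons are only
  meaningful at matched sensitivity, which is why reports pair the index
  with sensitivity across thresholds.
* The ONS-style ethnicity map and regimen dictionary are packaged,
  versioned stand-ins at realistic granularity, not reproductions of any
  official list.
* Haemoglobin, neutrophils and ALT are features only; no toxicity grading
  is attempted for them.
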