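# chemotox

Risk-stratification modelling and bias auditing for chemotherapy-induced
renal and hepatic dysfunction.

Patients on chemotherapy have blood taken before every cycle so that
treatment-related organ damage (rising creatinine, rising bilirubin) is
caught before the next dose. Most of those tests come back normal. A model
that reliably flags the minority of patients at high risk would let
low-risk patients skip some pre-cycle phlebotomy — but only if it works
across hospitals with different patient populations, across time, and
across patient subgroups. `chemotox` implements that full analysis as a
reusable, tested pipeline, exercised end to end on a synthetic multi-site
cohort generator, for biostatisticians and ML researchers who want to
develop or audit this class of clinical model.

## What it implements

* **Synthetic multi-site cohorts** (`generate_cohort()`): longitudinally
  coherent per-cycle blood panels (baseline + cycles 1–6) for configurable
  site profiles — per-site demographic/tumour mixes, site-shifted baseline
  creatinine, per-analyte toxicity event rates, cycle-dependent
  missingness, temporal drift. Injected events are recorded in a hidden
  ground-truth table so every downstream stage is verifiable.
* **Cohort construction** (`build_cohort()`): adults (≥ 18) on first-line
  treatment, ≥ 2 cycles, second cycle within 60 days, complete blood data;
  deterministic exclusion log; per-site summary tables
  (`summarize_cohort()`).
* **CTCAE-style toxicity grading** (`grade()`, `derive_labels()`): ladders
  with grade 1 at `max(1.5 × baseline, 1.5 × ULN)` (creatinine) or
  `1.5 × ULN` (bilirubin); the outcome label is the *first grade change
  toward toxicity*, recorded once per patient and analyte.
* **Two-framing regression models** (`framing_spec()`,
  `train_regressor()`): gradient-boosted trees (xgboost) predict the
  cycle-*n* analyte value from demographics plus labs at cycles 1–2
  (*fixed-early*) or cycles *n−1*, *n−2* (*rolling*), with
  training-set-only standardisation, patient-grouped cross-validation and
  a seeded hyperparameter search. Predictions become risk classes through
  a sensitivity-tuned decision boundary (`classify_risk()`): high risk iff
  the prediction reaches `1.4 × baseline` or `1.4 × ULN`.
* **Evaluation** (`confusion()`, `fbeta()`, `subgroup_metrics()`,
  `threshold_sweep()`): the F2 score

  `F2 = 5·TP / (5·TP + FP + 4·FN)`

  weights recall four times precision, matching the clinical preference
  for false positives over missed high-risk patients; subgroup tables
  count patient-cycle records and omit groups with fewer than 10.
* **Fairness audit** (`gei()`, `between_group_gei()`): per-record benefit
  `b = M(x) − y + 1` (FN → 0, FP → 2, correct → 1) feeds the Generalised
  Entropy Index `I^α(b) = 1/(nα(α−1)) Σ((b_i/μ)^α − 1)` and its
  between-group form over demographic partitions, swept across decision
  thresholds (`gei_threshold_curve()`).
* **Data shift and aggregation** (`compare_distributions()`,
  `compare_fine_vs_broad()`): standardized mean differences, KS statistics
  and total-variation distances for every feature across every site pair;
  and a paired experiment quantifying what coarsening ethnicity codes to
  broad ONS-style groups and regimens to size classes does to subgroup
  performance. `bias_audit()` assembles everything into a six-section
  machine-readable report.

## Worked example

```r
library(chemotox)
library(dplyr)

sites <- list(
  site_profile("city",  900, creatinine_shift = 0,
               toxicity_rates = c(creatinine = 0.15, bilirubin = 0.10)),
  site_profile("rural", 400, creatinine_shift = 8,
               toxicity_rates = c(creatinine = 0.08, bilirubin = 0.12)))
cohort <- generate_cohort(generator_config(sites, seed = 42)) |> build_cohort()
cohort
#> <chemo_cohort> 1300 patients, 2 sites, 9100 observation rows, 344 injected events

labels <- derive_labels(cohort)
summarize_cohort(cohort, labels) |>
  filter(statistic %in% c("n_patients", "sex_female", "creatinine_grade_changes"))
#>   site  statistic                value percent
#> 1 city  n_patients                 900    NA
#> 2 city  sex_female                 503    55.9
#> 3 city  creatinine_grade_changes   150    17
#> 4 rural n_patients                 400    NA
#> 5 rural sex_female                 235    58.8
#> 6 rural creatinine_grade_changes    26     6
```

Train a rolling-framing creatinine model on one site and evaluate it on
the other (an unseen-site external validation):

```r
framing <- framing_spec("rolling", "creatinine")
features <- build_features(cohort, framing)
splits <- make_splits(cohort, train_sites = "city", test_fraction = 0.2, seed = 42)
train <- semi_join(features, filter(splits, split == "train"), by = "patient_id") |>
  (\(d) { attributes(d)[c("feature_cols", "framing")] <-
            attributes(features)[c("feature_cols", "framing")]; d })()
model <- train_regressor(train, cv_folds = 5, search_budget = 5, seed = 42)
model
#> <risk_model> creatinine (rolling framing): 2880 training rows, 57 features
#>   best: depth 8, eta 0.044, 110 trees, subsample 0.90 (cv rmse 27.411)

records <- predict_risk(model, features) |>
  semi_join(filter(splits, split == "external"), by = "patient_id")
cs <- confusion(records$.pred_class, records$truth)
bind_cols(cs, metric_set(cs))
#>     tp    fp    fn    tn precision recall    f1    f2
#> 1   38    73    25  1464     0.342  0.603 0.437 0.523
```

F2 (0.52) sits well above precision because the 1.4× decision boundary is
deliberately conservative: of 63 true toxicity records the model misses 25
but flags 73 extra patients for a blood test, the preferred trade-off. The
fairness indices on the same external records are small — the model's
errors are spread evenly rather than concentrated in one group:

```r
b <- compute_benefits(records$.pred_class, records$truth)
c(gei = gei(b), between_sexes = between_group_gei(b, records$sex))
#>           gei between_sexes
#>  2.844283e-02  2.555523e-05

compare_distributions(cohort) |> filter(feature == "baseline_creatinine")
#>   feature             type    site_a site_b    smd    ks   tvd flagged
#> 1 baseline_creatinine numeric city   rural  -0.434 0.176    NA TRUE
```

The planted 8 µmol/L site shift in baseline creatinine is detected as an
SMD of −0.43 and flagged — exactly the kind of cross-site data shift the
audit machinery exists to surface before deployment.

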