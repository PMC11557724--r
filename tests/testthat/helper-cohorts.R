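# Shared fixture builders; everything is generated in code at test time.

quick_sites <- function(n = 300, rates = c(creatinine = 0.15, bilirubin = 0.1),
                        ...) {
  list(site_profile("site_a", n, toxicity_rates = rates, ...))
}

quick_cohort <- function(n = 300, seed = 11,
                         rates = c(creatinine = 0.15, bilirubin = 0.1), ...) {
  generate_cohort(generator_config(quick_sites(n, rates), seed = seed, ...))
}

# A handcrafted raw extract: complete 7-cycle observations with flat labs,
# easy to perturb for the inclusion/exclusion edge cases.
manual_patient <- function(id, age = 60, sex = "female", site = "m",
                           tumour = "breast") {
  tibble::tibble(patient_id = id, site = site, age = age, sex = sex,
                 ethnicity_fine = "British", height = 165, weight = 70,
                 tumour_type = tumour, regimen = "AC", n_drugs = 2L,
                 relative_dose_intensity = 0.95, first_line = TRUE,
                 comorb_diabetes = FALSE, comorb_cardiovascular = FALSE,
                 comorb_thyroid = FALSE, comorb_respiratory = FALSE,
                 comorb_arthritis = FALSE, comorb_autoimmune = FALSE)
}

manual_obs <- function(id, cycles = 0:6, gaps = rep(21, 5),
                       creatinine = 70, bilirubin = 9) {
  day <- c(-7, 0, cumsum(gaps))[match(cycles, 0:6)]
  tibble::tibble(patient_id = id, cycle = cycles, day_offset = day,
                 creatinine = creatinine, bilirubin = bilirubin,
                 haemoglobin = 130, anc = 4, alt = 20)
}

manual_cohort <- function(patients, observations) {
  structure(list(patients = patients, observations = observations,
                 events = NULL),
            class = "chemo_cohort")
}

# Random trajectory labelling oracle: first cycle whose grade exceeds the
# grade at ANY earlier cycle, found by scanning all (earlier, later) pairs.
oracle_first_change <- function(grades) {
  for (c in 2:length(grades)) {
    for (j in 1:(c - 1)) {
      if (grades[c] > grades[j]) return(c - 1L) # cycle index (0-based series)
    }
  }
  NA_integer_
}

# Train/evaluate convenience used by the heavier pipeline tests.
fit_eval <- function(cohort, framing, seed, search_budget = 3, cv_folds = 3,
                     test_fraction = 0.2) {
  feats <- build_features(cohort, framing)
  sp <- make_splits(cohort, test_fraction = test_fraction, seed = seed)
  keep_attrs <- function(df) {
    attr(df, "feature_cols") <- attr(feats, "feature_cols")
    attr(df, "framing") <- framing
    df
  }
  tr <- keep_attrs(feats[feats$patient_id %in%
                           sp$patient_id[sp$split == "train"], ])
  te <- keep_attrs(feats[feats$patient_id %in%
                           sp$patient_id[sp$split == "test"], ])
  model <- train_regressor(tr, cv_folds = cv_folds,
                           search_budget = search_budget, seed = seed)
  list(model = model, records = predict_risk(model, te), test = te)
}
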