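test_that("self-comparison of identical cohorts yields exact zeros", {
  co <- quick_cohort(n = 150, seed = 19)
  bt <- baseline_table(co)
  doubled <- dplyr::bind_rows(
    dplyr::mutate(bt, site = "x"),
    dplyr::mutate(bt, site = "y", patient_id = paste0(patient_id, "_y")))
  cmp <- compare_distributions(doubled)
  num <- dplyr::filter(cmp, type == "numeric")
  expect_true(all(num$smd == 0))
  expect_true(all(num$ks == 0))
  expect_true(all(dplyr::filter(cmp, type == "categorical")$tvd == 0))
  expect_false(any(cmp$flagged))
})

test_that("a planted +0.5 SD baseline creatinine shift is flagged", {
  labs <- default_baseline_labs()
  shift <- 0.5 * labs$creatinine[2]
  sites <- list(
    site_profile("a", 1000, toxicity_rates = c(creatinine = .1, bilirubin = .1)),
    site_profile("b", 1000, creatinine_shift = shift,
                 toxicity_rates = c(creatinine = .1, bilirubin = .1)))
  co <- generate_cohort(generator_config(sites, seed = 23))
  cmp <- compare_distributions(co)
  row <- dplyr::filter(cmp, feature == "baseline_creatinine")
  expect_true(row$flagged)
  expect_equal(abs(row$smd), 0.5, tolerance = 0.2)
  # untouched analytes stay unflagged
  expect_false(dplyr::filter(cmp, feature == "baseline_bilirubin")$flagged)
})

test_that("tumour mixes differing across sites reproduce generator frequencies", {
  sites <- list(
    site_profile("a", 1500,
                 tumour_mix = c(breast = .4, bowel = .34, dlbcl = .26,
                                lung = 0, ovarian = 0),
                 toxicity_rates = c(creatinine = .1, bilirubin = .1)),
    site_profile("b", 1500,
                 tumour_mix = c(breast = .13, bowel = .68, dlbcl = .19,
                                lung = 0, ovarian = 0),
                 toxicity_rates = c(creatinine = .1, bilirubin = .1)))
  co <- generate_cohort(generator_config(sites, seed = 29))
  p <- co$patients
  expect_lt(abs(mean(p$tumour_type[p$site == "b"] == "bowel") - 0.68), 0.03)
  cmp <- compare_distributions(co)
  expect_true(dplyr::filter(cmp, feature == "tumour_type")$flagged)
})

test_that("aggregation coarsens ethnicity and regimen, conserving counts", {
  co <- quick_cohort(n = 400, seed = 37)
  fine <- aggregate_subgroups(co$patients, aggregation_scheme("fine"))
  expect_identical(fine, co$patients) # fine mode is the identity

  broad <- aggregate_subgroups(co$patients, aggregation_scheme("broad"))
  expect_equal(nrow(broad), nrow(co$patients))
  map <- ethnicity_reference()
  expect_true(all(broad$ethnicity_fine %in% map$ethnicity_broad))
  # each broad group's count is the sum of its fine groups' counts
  expected <- table(map$ethnicity_broad[
    match(co$patients$ethnicity_fine, map$ethnicity_fine)])
  expect_equal(as.vector(table(broad$ethnicity_fine)[names(expected)]),
               as.vector(expected))

  one <- aggregate_subgroups(
    tibble::tibble(ethnicity_fine = "British", regimen = "AC", n_drugs = 2L),
    aggregation_scheme("broad"))
  expect_equal(one$ethnicity_fine, "White")
  expect_equal(one$regimen, "doublet")
  expect_equal(aggregate_subgroups(
    tibble::tibble(ethnicity_fine = "Irish", regimen = "FOLFOX", n_drugs = 3L),
    aggregation_scheme("broad"))$regimen, "triplet")

  expect_error(aggregate_subgroups(
    tibble::tibble(ethnicity_fine = "Martian", regimen = "AC", n_drugs = 2L),
    aggregation_scheme("broad")), "Martian")
})

test_that("fine vs broad comparison pairs identical validation records", {
  co <- build_cohort(quick_cohort(n = 250, seed = 41))
  cmpn <- compare_fine_vs_broad(co, framing_spec("fixed_early", "creatinine"),
                                seed = 2, cv_folds = 2, search_budget = 2)
  expect_s3_class(cmpn$fine, "subgroup_report")
  expect_equal(nrow(glance(cmpn)), 1)
  expect_equal(glance(cmpn)$delta,
               glance(cmpn)$f2_fine - glance(cmpn)$f2_broad)
  d <- tidy(cmpn)
  expect_true(all(c("f2_fine", "f2_broad", "delta") %in% names(d)))
  # reports are keyed on identical subgroup labels
  expect_setequal(paste(cmpn$fine$dimension, cmpn$fine$group),
                  paste(cmpn$broad$dimension, cmpn$broad$group))
})

test_that("the six-section bias audit assembles and serialises", {
  co <- quick_cohort(n = 120, seed = 43)
  rep_ <- bias_audit(
    multi_site_statistics = summarize_cohort(co),
    site_distribution_comparison = tibble::tibble(feature = "age", smd = 0.02),
    per_site_holdout_metrics = tibble::tibble(site = "site_a", f2 = 0.7),
    formal_fairness_measures = tibble::tibble(gei = 0.1, between_group = 0.02),
    deployment_restrictions = deployment_flags(
      tibble::tibble(site = "site_a", f2 = 0.7)),
    aggregation_effects = tibble::tibble(delta = 0.01))
  expect_named(rep_, c("multi_site_statistics", "site_distribution_comparison",
                       "per_site_holdout_metrics", "formal_fairness_measures",
                       "deployment_restrictions", "aggregation_effects"))
  expect_false(rep_$deployment_restrictions$restrict)
  path <- withr::local_tempfile(fileext = ".json")
  write_bias_audit(rep_, path)
  parsed <- jsonlite::read_json(path)
  expect_length(parsed, 6)
})
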