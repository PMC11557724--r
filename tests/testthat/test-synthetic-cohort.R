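test_that("generation is deterministic under a fixed seed, down to the bytes", {
  cfg <- generator_config(quick_sites(80), seed = 5)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$patients, b$patients)
  expect_identical(a$observations, b$observations)
  expect_identical(a$events, b$events)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(a, d1, include_events = TRUE)
  write_cohort(b, d2, include_events = TRUE)
  for (f in c("patients.csv", "observations.csv", "events.csv")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  rt <- read_cohort(d1)
  expect_equal(nrow(rt$patients), 80)
  expect_equal(nrow(rt$observations), 80 * 7)
})

test_that("zero toxicity rates produce an empty ground-truth event table", {
  co <- quick_cohort(n = 100, seed = 2,
                     rates = c(creatinine = 0, bilirubin = 0))
  expect_equal(nrow(co$events), 0)
  expect_false(any(derive_labels(co)$event))
})

test_that("labelled event prevalence tracks the configured rate at n = 2000", {
  co <- quick_cohort(n = 2000, seed = 7)
  lab <- derive_labels(co)
  prev <- mean(lab$event[lab$analyte == "creatinine"])
  expect_gte(prev, 0.13)
  expect_lte(prev, 0.17)
})

test_that("generated marginals recover the site profile", {
  prof <- site_profile("s", 2000, age = c(58, 18, 88, 13), sex_female = 0.65,
                       tumour_mix = c(breast = 0.4, bowel = 0.35, dlbcl = 0.25,
                                      lung = 0, ovarian = 0))
  co <- generate_cohort(generator_config(list(prof), seed = 21))
  p <- co$patients
  expect_lt(abs(mean(p$sex == "female") - 0.65), 0.02)
  expect_lt(abs(mean(p$tumour_type == "breast") - 0.4), 0.02)
  expect_lt(abs(mean(p$tumour_type == "dlbcl") - 0.25), 0.02)
  expect_lte(abs(median(p$age) - 58), 2)
})

test_that("the labeller recovers injected events when missingness is zero", {
  co <- quick_cohort(n = 1000, seed = 13)
  lab <- derive_labels(co)
  hit <- dplyr::inner_join(co$events, lab, by = c("patient_id", "analyte"))
  expect_gte(mean(hit$event & hit$first_change_cycle == hit$event_cycle), 0.95)
})

test_that("invalid configuration errors name the offending field", {
  expect_error(site_profile("x", 10, sex_female = 1.2), "sex_female")
  expect_error(site_profile("x", 10,
                            tumour_mix = c(breast = 0.6, bowel = 0.6, dlbcl = 0,
                                           lung = 0, ovarian = -0.2)),
               "tumour_mix")
  expect_error(site_profile("x", 0), "n_patients")
  expect_error(generator_config(quick_sites(10), autocorrelation = 1),
               "autocorrelation")
  expect_error(
    generator_config(quick_sites(10),
                     toxicity_effect = list(cycle_probs = rep(0.25, 4),
                                            multiplier = 1.2)),
    "multiplier")
})

test_that("missingness blanks panels at the curve's per-cycle rates", {
  co <- quick_cohort(n = 5000, seed = 31,
                     rates = c(creatinine = 0, bilirubin = 0))
  curve <- c(0, 0, 0.1, 0.2, 0.3, 0.4, 0.5)

  unchanged <- apply_missingness(co$observations, rep(0, 7), seed = 1)
  expect_identical(unchanged, co$observations)

  blanked <- apply_missingness(co$observations, curve, seed = 1)
  rates <- blanked |>
    dplyr::group_by(cycle) |>
    dplyr::summarise(miss = mean(is.na(creatinine)))
  expect_true(all(abs(rates$miss - curve) <= 0.02))
  expect_false(anyNA(blanked$creatinine[blanked$cycle == 0]))
  # whole panel goes missing together
  expect_identical(is.na(blanked$creatinine), is.na(blanked$alt))

  expect_identical(blanked, apply_missingness(co$observations, curve, seed = 1))
  expect_error(apply_missingness(co$observations, rev(curve), seed = 1),
               "monotone")
})

test_that("distinct baseline creatinine shifts surface as cross-site shift", {
  sites <- list(
    site_profile("a", 600, creatinine_shift = 0,
                 toxicity_rates = c(creatinine = 0.1, bilirubin = 0.1)),
    site_profile("b", 600, creatinine_shift = 8,
                 toxicity_rates = c(creatinine = 0.1, bilirubin = 0.1)))
  co <- generate_cohort(generator_config(sites, seed = 17))
  cmp <- compare_distributions(co)
  row <- dplyr::filter(cmp, feature == "baseline_creatinine")
  expect_gt(abs(row$smd), 0.1)
  expect_true(row$flagged)
})
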