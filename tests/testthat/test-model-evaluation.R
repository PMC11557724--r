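test_that("confusion counts enumerate correctly", {
  cs <- confusion(c("high", "high", "high", "low", "low"),
                  c("event", "event", "no_event", "event", "no_event"))
  expect_equal(unlist(cs[c("tp", "fp", "fn", "tn")]),
               c(tp = 2L, fp = 1L, fn = 1L, tn = 1L))
  perfect <- confusion(c("high", "low"), c("event", "no_event"))
  expect_equal(perfect$fp + perfect$fn, 0L)
  empty <- confusion(character(), character())
  expect_equal(sum(unlist(empty)), 0L)
  expect_error(confusion("high", c("event", "event")), "length")
})

test_that("fbeta matches its closed form and the 0/0 conventions", {
  cs <- tibble::tibble(tp = 7, fp = 3, fn = 2, tn = 0)
  expect_equal(fbeta(cs, 2), 35 / 46)
  expect_equal(fbeta(tibble::tibble(tp = 5, fp = 0, fn = 0), 2), 1)
  expect_equal(fbeta(tibble::tibble(tp = 0, fp = 5, fn = 5), 2), 0)
  expect_equal(fbeta(tibble::tibble(tp = 0, fp = 0, fn = 0), 2), 0)
  ms <- metric_set(tibble::tibble(tp = 0, fp = 0, fn = 0, tn = 10))
  expect_equal(unlist(ms), c(precision = 0, recall = 0, f1 = 0, f2 = 0))
  expect_error(fbeta(cs, beta = 0), "positive")
})

test_that("F-beta relations hold on random confusion tables", {
  set.seed(123)
  for (i in 1:2000) {
    cs <- tibble::tibble(tp = rpois(1, 5), fp = rpois(1, 5), fn = rpois(1, 5),
                         tn = rpois(1, 5))
    ms <- metric_set(cs)
    # beta = 1 equals the harmonic mean of precision and recall
    if (ms$precision + ms$recall > 0) {
      expect_equal(ms$f1, 2 * ms$precision * ms$recall /
                     (ms$precision + ms$recall), tolerance = 1e-12)
    }
    if (cs$tp > 0) {
      if (ms$recall > ms$precision) expect_gt(ms$f2, ms$f1)
      if (ms$recall < ms$precision) expect_lt(ms$f2, ms$f1)
      if (ms$recall == ms$precision) expect_equal(ms$f2, ms$f1)
    }
  }
})

test_that("threshold sweep agrees with direct reclassification at each point", {
  set.seed(31)
  n <- 400
  pred <- runif(n, 40, 260)
  base <- runif(n, 50, 120)
  truth <- ifelse(runif(n) < 0.2, "event", "no_event")
  uln <- 104
  ms <- c(seq(0.3, 4, by = 0.2), 7) # 7 exceeds every prediction/threshold ratio
  sw <- threshold_sweep(pred, base, truth, decision_rule("creatinine", uln = uln),
                        multipliers = ms)
  for (i in seq_along(ms)) {
    flag <- pred >= pmin(ms[i] * base, ms[i] * uln)
    expect_equal(sw$tp[i], sum(flag & truth == "event"))
    expect_equal(sw$fp[i], sum(flag & truth == "no_event"))
  }
  expect_equal(sw$recall[1], 1) # multiplier below every ratio flags everyone
  expect_equal(sw$recall[nrow(sw)], 0)
  expect_equal(sw$precision[nrow(sw)], 0) # 0/0 convention
  expect_error(threshold_sweep(pred, base, truth,
                               decision_rule("creatinine"), multipliers = c(2, 1)),
               "ascending")
})

test_that("subgroup metrics omit small groups and conserve counts", {
  set.seed(77)
  n <- 200
  rec <- tibble::tibble(
    .pred_class = sample(c("high", "low"), n, replace = TRUE),
    truth = sample(c("event", "no_event"), n, replace = TRUE, prob = c(.2, .8)),
    sex = sample(c("female", "male"), n, replace = TRUE),
    ethnicity_fine = sample(c("British", "Irish", "Indian"), n, TRUE,
                            prob = c(.9, .06, .04)),
    age = sample(c(18, 19, 35, 62, 95), n, TRUE),
    tumour_type = "breast")
  rep_ <- subgroup_metrics(rec, min_n = 10)
  overall <- confusion(rec$.pred_class, rec$truth)
  for (dim in unique(rep_$dimension)) {
    sub <- dplyr::filter(rep_, dimension == dim)
    expect_equal(sum(sub$n_records), n)
    expect_equal(sum(sub$tp), overall$tp)
    expect_equal(sum(sub$fn), overall$fn)
  }
  expect_true(all(is.na(rep_$f2[rep_$omitted])))
  expect_true(all(rep_$omitted == (rep_$n_records < 10)))
  # 18-19 year olds land in the 10-19 decade; 95 in 90+
  ages <- dplyr::filter(rep_, dimension == "age_decade")
  expect_true("10-19" %in% ages$group)
  expect_true("90+" %in% ages$group)
  # a single group covering everything reproduces the overall metrics
  one <- subgroup_metrics(dplyr::mutate(rec, all = "all"),
                          dimensions = c(all = "all"), min_n = 10)
  expect_equal(one$f2, fbeta(overall, 2))
  expect_error(subgroup_metrics(rec, dimensions = c(x = "nope")), "unknown")
})

test_that("exactly nine records in a group triggers omission", {
  rec <- tibble::tibble(
    .pred_class = rep("high", 19), truth = rep("event", 19),
    sex = rep(c("female", "male"), c(9, 10)))
  rep_ <- subgroup_metrics(rec, dimensions = c(sex = "sex"), min_n = 10)
  expect_true(rep_$omitted[rep_$group == "female"])
  expect_false(rep_$omitted[rep_$group == "male"])
})
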