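test_that("grading follows the ladder rungs", {
  cre <- grade_ladder("creatinine", uln = 104)
  bil <- grade_ladder("bilirubin", uln = 21)
  expect_equal(grade(104, 104, cre), 0)               # at ULN, below every rung
  expect_equal(grade(170, 100, cre), 1)               # > max(150, 156), < 312
  expect_equal(grade(170, 120, cre), 0)               # baseline arm lifts rung to 180
  expect_equal(grade(400, 100, cre), 2)               # > 3 x ULN
  expect_equal(grade(70, 8, bil), 2)                  # > 63, < 210
  expect_equal(grade(c(20, 32, 64, 211), rep(8, 4), bil), c(0, 1, 2, 3))
  expect_error(grade(-1, 70, cre), "positive")
  expect_error(grade(70, 0, cre), "positive")
})

test_that("grade is monotone in value and risk class in prediction", {
  set.seed(42)
  cre <- grade_ladder("creatinine")
  for (i in 1:200) {
    baseline <- runif(1, 40, 200)
    v <- sort(runif(10, 20, 800))
    g <- grade(v, rep(baseline, 10), cre, sex = sample(c("female", "male"), 1))
    expect_true(all(diff(g) >= 0))
  }
  rule <- decision_rule("creatinine", uln = 104)
  cls <- classify_risk(seq(50, 300, by = 10), 80, rule)
  expect_true(all(diff(cls == "high") >= 0))
})

test_that("labels record one event, at the first change toward toxicity", {
  # craft bilirubin trajectories hitting exact grade sequences (ULN 21)
  g2val <- function(g) c(10, 40, 70, 250)[g + 1] # grades 0,1,2,3
  mk <- function(id, grades) {
    o <- manual_obs(id)
    o$bilirubin <- g2val(grades)
    o
  }
  patients <- dplyr::bind_rows(manual_patient("worsen"),
                               manual_patient("improve"),
                               manual_patient("flat"),
                               manual_patient("rebound"))
  obs <- dplyr::bind_rows(
    mk("worsen", c(0, 0, 0, 1, 1, 2, 2)),   # first change at cycle 3
    mk("improve", c(1, 1, 0, 0, 0, 0, 0)),  # improvement only: no event
    mk("flat", rep(0, 7)),
    mk("rebound", c(1, 1, 0, 0, 1, 0, 1)))
  lab <- derive_labels(manual_cohort(patients, obs)) |>
    dplyr::filter(analyte == "bilirubin")
  by_id <- function(id) dplyr::filter(lab, patient_id == id)
  expect_equal(by_id("worsen")$first_change_cycle, 3L)
  expect_false(by_id("improve")$event)
  expect_false(by_id("flat")$event)
  # a rise back above the best (lowest) grade seen so far is an event
  expect_equal(by_id("rebound")$first_change_cycle, 4L)
})

test_that("a worsen-recover-worsen patient yields a single event at the first rise", {
  patients <- manual_patient("p")
  o <- manual_obs("p")
  o$bilirubin <- c(10, 10, 40, 10, 10, 70, 70) # grades 0,0,1,0,0,2,2
  lab <- derive_labels(manual_cohort(patients, o)) |>
    dplyr::filter(analyte == "bilirubin")
  expect_true(lab$event)
  expect_equal(lab$first_change_cycle, 2L)
})

test_that("labelling agrees with a brute-force all-pairs scan on random trajectories", {
  set.seed(99)
  n <- 2000
  vals <- matrix(exp(runif(n * 7, log(5), log(300))), n, 7)
  patients <- dplyr::bind_rows(lapply(sprintf("r%04d", 1:n), manual_patient))
  obs <- dplyr::bind_rows(lapply(1:n, function(i) {
    o <- manual_obs(sprintf("r%04d", i))
    o$bilirubin <- vals[i, ]
    o
  }))
  lab <- derive_labels(manual_cohort(patients, obs)) |>
    dplyr::filter(analyte == "bilirubin") |>
    dplyr::arrange(patient_id)
  lad <- grade_ladder("bilirubin")
  expected <- vapply(seq_len(n), function(i) {
    g <- grade(vals[i, ], rep(vals[i, 1], 7), lad)
    oracle_first_change(g)
  }, 0L)
  expect_equal(lab$first_change_cycle, expected)
  expect_equal(lab$event, !is.na(expected))
})

test_that("incomplete trajectories are a precondition error", {
  patients <- manual_patient("p")
  expect_error(derive_labels(manual_cohort(patients, manual_obs("p", cycles = 0:5))),
               "incomplete")
  o <- manual_obs("p")
  o$creatinine[3] <- NA
  expect_error(derive_labels(manual_cohort(patients, o)), "missing")
})

test_that("the 1.4x decision rule flags on baseline OR ULN, inclusive boundary", {
  cre <- decision_rule("creatinine", uln = 104)
  bil <- decision_rule("bilirubin", uln = 21)
  expect_equal(classify_risk(120, 80, cre), "high")   # 120 >= 1.4 x 80
  expect_equal(classify_risk(111, 80, cre), "low")    # below 112 and 145.6
  expect_equal(classify_risk(30, 9, bil), "high")     # 30 >= 29.4
  expect_equal(classify_risk(1.4 * 21, 9, bil), "high") # boundary inclusive
  expect_equal(classify_risk(1.4 * 21 - 1e-9, 9, bil), "low")
  # effective creatinine threshold is min(1.4 b, 1.4 ULN)
  expect_equal(risk_threshold(cre, 80), 112)
  expect_equal(risk_threshold(cre, 200), 1.4 * 104)
})

test_that("lowering the multiplier never decreases sensitivity", {
  set.seed(7)
  pred <- runif(500, 40, 260)
  base <- runif(500, 50, 120)
  truth <- sample(c("event", "no_event"), 500, replace = TRUE)
  sw <- threshold_sweep(pred, base, truth, decision_rule("creatinine", uln = 104),
                        multipliers = seq(0.8, 3, by = 0.1))
  expect_true(all(diff(sw$recall) <= 1e-12))
})
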