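# Feature construction under the two prediction framings, standardisation,
# patient-level splitting and gradient-boosted regression of cycle-n analyte
# values. The learner (xgboost) sits behind a fit/predict contract; the
# package's own computation is the framing, thresholding, metrics and
# fairness machinery around it.

#' Prediction framing
#'
#' Two framings for predicting the analyte value at a target cycle n in 3--6:
#' `fixed_early` always uses the labs from cycles 1 and 2, `rolling` uses the
#' two cycles immediately preceding the target (n-1 and n-2). Every
#' patient-cycle combination is a separate sample, so a patient observed
#' through cycle 6 contributes one row per requested target cycle.
#'
#' @param mode `"rolling"` or `"fixed_early"`.
#' @param analyte Regression target analyte.
#' @param target_cycles Integer target cycles, subset of 3:6.
#' @return A `framing_spec` object.
#' @export
framing_spec <- function(mode = c("rolling", "fixed_early"),
                         analyte = c("creatinine", "bilirubin"),
                         target_cycles = 3:6) {
  mode <- match.arg(mode)
  analyte <- match.arg(analyte)
  if (!all(target_cycles %in% 3:6)) {
    domain_abort("`target_cycles` must lie in 3:6")
  }
  structure(list(mode = mode, analyte = analyte,
                 target_cycles = sort(unique(as.integer(target_cycles)))),
            class = "framing_spec")
}

#' Build the model feature matrix
#'
#' One row per (patient, target cycle): demographics (age, sex, height,
#' weight, relative dose intensity, comorbidity flags), one-hot ethnicity /
#' tumour type / regimen at the granularity of the active aggregation scheme,
#' the five baseline labs, and the five labs at each of the two framing
#' cycles (`prev1_` = the later of the two). The regression target
#' `target_value` is the observed analyte value at the target cycle in
#' natural units.
#'
#' @param cohort A complete `chemo_cohort` (after [build_cohort()]).
#' @param framing A [framing_spec()].
#' @param scheme An [aggregation_scheme()]; `"broad"` coarsens ethnicity and
#'   regimen before encoding.
#' @return Tibble with metadata columns (`patient_id`, `site`, `target_cycle`,
#'   `sex`, `age`, `ethnicity_fine`, `tumour_type`, `regimen`, `n_drugs`,
#'   `baseline`, `target_value`) plus numeric feature columns listed in
#'   `attr(, "feature_cols")`.
#' @export
build_features <- function(cohort, framing,
                           scheme = aggregation_scheme("fine")) {
  stopifnot(inherits(framing, "framing_spec"))
  patients <- aggregate_subgroups(cohort$patients, scheme)
  obs <- cohort$observations
  if (anyNA(obs[analytes()])) {
    domain_abort("observations contain missing labs; run remove_missing_bloods() first")
  }
  wide <- obs |>
    dplyr::select(-"day_offset") |>
    tidyr::pivot_wider(names_from = "cycle",
                       values_from = dplyr::all_of(analytes()),
                       names_glue = "c{cycle}_{.value}")

  onehot <- function(x, prefix) {
    lv <- sort(unique(x))
    cols <- lapply(lv, function(l) as.numeric(x == l))
    names(cols) <- make.names(paste0(prefix, "_", lv))
    as_tibble(cols)
  }
  comorb_cols <- grep("^comorb_", names(patients), value = TRUE)
  static <- patients |>
    dplyr::transmute(
      .data$patient_id, .data$site, .data$sex, .data$age,
      ethnicity_fine = .data$ethnicity_fine, .data$tumour_type,
      .data$regimen, .data$n_drugs,
      f_age = .data$age, f_male = as.numeric(.data$sex == "male"),
      f_height = .data$height, f_weight = .data$weight,
      f_rdi = .data$relative_dose_intensity) |>
    dplyr::bind_cols(
      stats::setNames(lapply(comorb_cols, function(cc) as.numeric(patients[[cc]])),
                      paste0("f_", comorb_cols)),
      onehot(patients$ethnicity_fine, "eth"),
      onehot(patients$tumour_type, "tum"),
      onehot(patients$regimen, "reg"))

  rows <- dplyr::bind_rows(lapply(framing$target_cycles, function(tc) {
    prev <- if (framing$mode == "rolling") c(tc - 1, tc - 2) else c(2, 1)
    lab_cols <- c(paste0("c0_", analytes()),
                  paste0("c", prev[1], "_", analytes()),
                  paste0("c", prev[2], "_", analytes()))
    labs <- wide[, c("patient_id", lab_cols, paste0("c", tc, "_", framing$analyte))]
    names(labs) <- c("patient_id",
                     paste0("f_base_", analytes()),
                     paste0("f_prev1_", analytes()),
                     paste0("f_prev2_", analytes()),
                     "target_value")
    labs$target_cycle <- tc
    labs$f_target_cycle <- as.numeric(tc)
    labs
  }))
  out <- dplyr::inner_join(static, rows, by = "patient_id") |>
    dplyr::mutate(baseline = .data[[paste0("f_base_", framing$analyte)]]) |>
    dplyr::arrange(.data$patient_id, .data$target_cycle)
  feature_cols <- grep("^(f_|eth_|tum_|reg_)", names(out), value = TRUE)
  attr(out, "feature_cols") <- feature_cols
  attr(out, "framing") <- framing
  attr(out, "scheme_active") <- scheme$active
  out
}

#' Feature standardisation (training rows only)
#'
#' Removes the mean and scales to unit variance, with parameters estimated on
#' the training rows only so validation data never leak into the transform.
#' Constant features are flagged and mapped to zero.
#'
#' @param data A feature tibble (from [build_features()]).
#' @param cols Feature columns; defaults to `attr(data, "feature_cols")`.
#' @return `fit_standardizer()`: a `standardizer` with per-feature means, SDs
#'   and constant flags.
#' @export
fit_standardizer <- function(data, cols = attr(data, "feature_cols")) {
  if (nrow(data) < 2) domain_abort("need at least 2 rows to fit a standardizer")
  means <- vapply(cols, function(cc) mean(data[[cc]], na.rm = TRUE), 0)
  sds <- vapply(cols, function(cc) sd(data[[cc]], na.rm = TRUE), 0)
  constant <- !is.finite(sds) | sds == 0
  structure(list(cols = cols, means = means, sds = sds, constant = constant),
            class = "standardizer")
}

#' @rdname fit_standardizer
#' @param params A fitted `standardizer`.
#' @return `apply_standardizer()`: `data` with the feature columns replaced by
#'   their standardised values.
#' @export
apply_standardizer <- function(params, data) {
  stopifnot(inherits(params, "standardizer"))
  for (i in seq_along(params$cols)) {
    cc <- params$cols[i]
    data[[cc]] <- if (params$constant[i]) {
      rep(0, nrow(data))
    } else {
      (data[[cc]] - params$means[i]) / params$sds[i]
    }
  }
  data
}

#' Patient-level train/test/external split
#'
#' Patients at the training sites are split train/test at the patient level
#' (all of a patient's per-cycle rows land on the same side); patients at all
#' other sites are marked `external` (unseen-site / temporal validation).
#'
#' @param patients Patients tibble or `chemo_cohort`.
#' @param train_sites Sites contributing train/test patients (default: all).
#' @param external_sites Sites that must be held out entirely; overlapping
#'   with `train_sites` is a configuration error.
#' @param test_fraction Fraction of training-site patients held out, per site.
#' @param seed Integer seed (deterministic assignment).
#' @return Tibble `patient_id`, `site`, `split` in
#'   `c("train", "test", "external")`.
#' @export
make_splits <- function(patients, train_sites = NULL, external_sites = NULL,
                        test_fraction = 0.2, seed = 1L) {
  if (inherits(patients, "chemo_cohort")) patients <- patients$patients
  if (test_fraction <= 0 || test_fraction >= 1) {
    config_abort("test_fraction", "must be in (0, 1)")
  }
  train_sites <- train_sites %||% unique(patients$site)
  if (length(bad <- intersect(train_sites, external_sites))) {
    config_abort("external_sites",
                 sprintf("overlaps train_sites: %s", paste(bad, collapse = ", ")))
  }
  if (!all(train_sites %in% patients$site)) {
    config_abort("train_sites", "contains sites absent from the cohort")
  }
  with_local_seed(seed, {
    patients |>
      dplyr::select("patient_id", "site") |>
      dplyr::group_by(.data$site) |>
      dplyr::mutate(split = if (.data$site[1] %in% train_sites) {
        n <- dplyr::n()
        n_test <- round(test_fraction * n)
        ifelse(seq_len(n) %in% sample.int(n, n_test), "test", "train")
      } else {
        "external"
      }) |>
      dplyr::ungroup()
  })
}

#' @rdname train_regressor
#' @export
default_search_space <- function() {
  list(max_depth = c(2L, 8L), eta = c(0.01, 0.3), nrounds = c(50L, 500L),
       subsample = c(0.5, 1))
}

sample_trial <- function(space) {
  list(max_depth = sample(space$max_depth[1]:space$max_depth[2], 1),
       eta = exp(runif(1, log(space$eta[1]), log(space$eta[2]))),
       nrounds = sample(space$nrounds[1]:space$nrounds[2], 1),
       subsample = runif(1, space$subsample[1], space$subsample[2]))
}

xgb_fit <- function(x, y, trial, nthread) {
  xgboost::xgb.train(
    params = list(objective = "reg:squarederror", max_depth = trial$max_depth,
                  eta = trial$eta, subsample = trial$subsample,
                  nthread = nthread),
    data = xgboost::xgb.DMatrix(x, label = y), nrounds = trial$nrounds,
    verbose = 0)
}

#' Train a per-analyte gradient-boosted regressor
#'
#' Standardises the features (training rows only), runs a seeded random
#' search over the hyperparameter space scored by patient-grouped K-fold
#' cross-validated RMSE, then refits the best configuration on all training
#' rows. Cross-validation folds are grouped by patient so a patient's rolling
#' samples never straddle a fold boundary. Predictions are continuous analyte
#' values in natural units.
#'
#' @param features Training-row feature tibble from [build_features()].
#' @param cv_folds Number of patient-grouped CV folds (default 10).
#' @param search_budget Number of random-search trials (>= 1).
#' @param seed Integer seed; fixed seed and budget give identical chosen
#'   hyperparameters.
#' @param space Search space, see [default_search_space()]: tree depth 2--8,
#'   learning rate 0.01--0.3 (log scale), 50--500 trees, subsample 0.5--1.
#' @param nthread Threads for xgboost (1 keeps results reproducible).
#' @return A `risk_model` bundle: fitted booster, standardizer, feature list,
#'   search trials, chosen hyperparameters and CV score.
#' @export
train_regressor <- function(features, cv_folds = 10, search_budget = 20,
                            seed = 1L, space = default_search_space(),
                            nthread = 1) {
  if (search_budget < 1) config_abort("search_budget", "must be >= 1")
  if (nrow(features) < 50) {
    domain_abort("need at least 50 training rows to fit a risk model")
  }
  cols <- attr(features, "feature_cols")
  framing <- attr(features, "framing")
  std <- fit_standardizer(features, cols)
  xs <- apply_standardizer(std, features)
  x <- as.matrix(xs[, cols])
  y <- features$target_value

  with_local_seed(seed, {
    ids <- unique(features$patient_id)
    cv_folds <- min(cv_folds, length(ids))
    fold_of <- sample(rep_len(seq_len(cv_folds), length(ids)))
    fold <- fold_of[match(features$patient_id, ids)]

    trials <- vector("list", search_budget)
    for (t in seq_len(search_budget)) {
      trial <- sample_trial(space)
      errs <- vapply(seq_len(cv_folds), function(k) {
        tr <- fold != k
        fit <- xgb_fit(x[tr, , drop = FALSE], y[tr], trial, nthread)
        pred <- predict(fit, xgboost::xgb.DMatrix(x[!tr, , drop = FALSE]))
        sqrt(mean((pred - y[!tr])^2))
      }, 0)
      trials[[t]] <- c(trial, list(cv_rmse = mean(errs)))
    }
    trials <- dplyr::bind_rows(lapply(trials, as_tibble))
    best <- as.list(trials[which.min(trials$cv_rmse), ])
    booster <- xgb_fit(x, y, best, nthread)

    structure(
      list(booster = booster, standardizer = std, feature_cols = cols,
           trials = trials, best = best, analyte = framing$analyte,
           mode = framing$mode, cv_folds = cv_folds, seed = seed,
           n_train = nrow(features)),
      class = "risk_model")
  })
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf(
    "<risk_model> %s (%s framing): %d training rows, %d features\n  best: depth %d, eta %.3f, %d trees, subsample %.2f (cv rmse %.3f)\n",
    x$analyte, x$mode, x$n_train, length(x$feature_cols), x$best$max_depth,
    x$best$eta, x$best$nrounds, x$best$subsample, x$best$cv_rmse))
  invisible(x)
}

#' @rdname train_regressor
#' @param object A `risk_model`.
#' @param newdata Feature tibble to predict on.
#' @param ... Unused.
#' @return `predict()`: numeric predicted analyte values in natural units.
#' @export
predict.risk_model <- function(object, newdata, ...) {
  xs <- apply_standardizer(object$standardizer, newdata)
  predict(object$booster,
          xgboost::xgb.DMatrix(as.matrix(xs[, object$feature_cols])))
}

#' Predict, classify and attach ground truth
#'
#' Runs a fitted model over a feature set, classifies each prediction with
#' the decision rule, and attaches the per-record ground truth: whether the
#' observed target-cycle value constitutes a CTCAE-style grade >= 1 toxicity
#' relative to the patient's baseline.
#'
#' @param model A `risk_model`.
#' @param features Feature tibble (same framing/scheme as training).
#' @param rule A [decision_rule()]; default 1.4x for the model's analyte.
#' @param ladder Grade ladder for the ground truth; default 1.5x CTCAE-style.
#' @return The metadata columns plus `.pred`, `.pred_class` (`high`/`low`) and
#'   `truth` (`event`/`no_event`).
#' @export
predict_risk <- function(model, features,
                         rule = decision_rule(model$analyte),
                         ladder = grade_ladder(model$analyte)) {
  pred <- predict(model, features)
  truth_grade <- grade(features$target_value, features$baseline, ladder,
                       sex = features$sex)
  features |>
    dplyr::select(dplyr::any_of(c("patient_id", "site", "target_cycle", "sex",
                                  "age", "ethnicity_fine", "tumour_type",
                                  "regimen", "n_drugs", "baseline",
                                  "target_value"))) |>
    dplyr::mutate(
      .pred = pred,
      .pred_class = classify_risk(pred, .data$baseline, rule, sex = .data$sex),
      truth = ifelse(truth_grade >= 1, "event", "no_event"))
}
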