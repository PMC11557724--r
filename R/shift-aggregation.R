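# Cross-site / temporal feature-distribution shift, and the fine-vs-broad
# subgroup-aggregation experiment.

#' Patients with baseline labs attached
#'
#' Joins each patient's cycle-0 blood panel (as `baseline_*` columns) onto the
#' patients table so that distribution comparisons cover all available
#' features — baseline labs included — not just demographics.
#'
#' @param cohort A `chemo_cohort`.
#' @return Patients tibble with five `baseline_*` columns.
#' @export
baseline_table <- function(cohort) {
  base <- cohort$observations |>
    dplyr::filter(.data$cycle == 0) |>
    dplyr::select("patient_id", dplyr::all_of(analytes())) |>
    dplyr::rename_with(~ paste0("baseline_", .x), dplyr::all_of(analytes()))
  dplyr::left_join(cohort$patients, base, by = "patient_id")
}

#' Compare feature distributions across sites
#'
#' For every feature and every unordered pair of sites: numeric features get
#' the standardized mean difference (SMD, pooled-SD denominator) and the
#' two-sample Kolmogorov--Smirnov statistic; categorical features get the
#' total variation distance (TVD) between category frequency tables.
#' Comparing a distribution with itself gives exact zeros. Features whose
#' |SMD| (or TVD) exceeds the threshold are flagged as shifted.
#'
#' @param data A tibble of per-patient features with a site column, e.g.
#'   [baseline_table()] output, or a `chemo_cohort` (converted via
#'   [baseline_table()]).
#' @param by Grouping column (default `"site"`).
#' @param features Columns to compare; default every column except ids,
#'   `by`, and the regimen drug-list helper columns.
#' @param smd_threshold Flagging threshold (default 0.1).
#' @return A `shift_comparison` tibble: `feature`, `type`, `site_a`, `site_b`,
#'   `smd`, `ks`, `tvd`, `flagged`.
#' @export
compare_distributions <- function(data, by = "site", features = NULL,
                                  smd_threshold = 0.1) {
  if (inherits(data, "chemo_cohort")) data <- baseline_table(data)
  if (!by %in% names(data)) domain_abort(sprintf("column `%s` not found", by))
  features <- features %||%
    setdiff(names(data), c("patient_id", by, "first_line"))
  if (length(bad <- setdiff(features, names(data)))) {
    domain_abort(sprintf("schema mismatch: missing feature(s) %s",
                         paste(bad, collapse = ", ")))
  }
  sites <- sort(unique(as.character(data[[by]])))
  if (length(sites) < 2) domain_abort("need at least 2 sites to compare")
  pairs <- utils::combn(sites, 2, simplify = FALSE)

  out <- map_dfr(features, function(ft) {
    x <- data[[ft]]
    numeric_ft <- is.numeric(x)
    map_dfr(pairs, function(pr) {
      xa <- x[data[[by]] == pr[1]]
      xb <- x[data[[by]] == pr[2]]
      if (numeric_ft) {
        xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
        pooled <- sqrt((sd(xa)^2 + sd(xb)^2) / 2)
        smd <- if (!is.finite(pooled) || pooled == 0) 0 else
          (mean(xa) - mean(xb)) / pooled
        ks <- if (length(xa) && length(xb)) {
          suppressWarnings(unname(ks.test(xa, xb)$statistic))
        } else {
          NA_real_
        }
        tibble(feature = ft, type = "numeric", site_a = pr[1], site_b = pr[2],
               smd = smd, ks = ks, tvd = NA_real_,
               flagged = abs(smd) > smd_threshold)
      } else {
        xa <- as.character(xa); xb <- as.character(xb)
        xa[is.na(xa)] <- "(missing)"; xb[is.na(xb)] <- "(missing)"
        lv <- union(xa, xb)
        pa <- table(factor(xa, lv)) / length(xa)
        pb <- table(factor(xb, lv)) / length(xb)
        tvd <- sum(abs(pa - pb)) / 2
        tibble(feature = ft, type = "categorical", site_a = pr[1],
               site_b = pr[2], smd = NA_real_, ks = NA_real_, tvd = tvd,
               flagged = tvd > smd_threshold)
      }
    })
  })
  class(out) <- c("shift_comparison", class(tibble()))
  attr(out, "smd_threshold") <- smd_threshold
  out
}

#' Subgroup aggregation scheme
#'
#' Controls categorical granularity: `fine` keeps exact ethnicity codes and
#' named regimens; `broad` coarsens ethnicity to its ONS-style broad group
#' (via the packaged many-to-one map) and regimens to their size class by
#' drug count (singlet, doublet, triplet or quartet).
#'
#' @param active `"fine"` or `"broad"`.
#' @param ethnicity_map Tibble with `ethnicity_fine`, `ethnicity_broad`.
#' @return An `aggregation_scheme` object.
#' @export
aggregation_scheme <- function(active = c("fine", "broad"),
                               ethnicity_map = ethnicity_reference()) {
  active <- match.arg(active)
  structure(list(active = active, ethnicity_map = ethnicity_map),
            class = "aggregation_scheme")
}

regimen_size_classes <- c("singlet", "doublet", "triplet", "quartet")

#' Coarsen record categories under a scheme
#'
#' In `broad` mode, replaces each record's fine ethnicity code with its broad
#' group and its regimen name with its size class; record counts are
#' conserved and every broad group's count is the sum of its fine groups'.
#' In `fine` mode the records are returned unchanged.
#'
#' @param records Tibble with `ethnicity_fine`, `regimen` and `n_drugs`.
#' @param scheme An [aggregation_scheme()].
#' @return The records, coarsened when the scheme is broad.
#' @export
#' @examples
#' df <- tibble::tibble(ethnicity_fine = "British", regimen = "AC", n_drugs = 2)
#' aggregate_subgroups(df, aggregation_scheme("broad"))
aggregate_subgroups <- function(records, scheme) {
  stopifnot(inherits(scheme, "aggregation_scheme"))
  if (scheme$active == "fine") return(records)
  m <- match(records$ethnicity_fine, scheme$ethnicity_map$ethnicity_fine)
  if (anyNA(m)) {
    domain_abort(sprintf(
      "unmapped ethnicity code(s): %s",
      paste(unique(records$ethnicity_fine[is.na(m)]), collapse = ", ")))
  }
  if (any(!records$n_drugs %in% 1:4)) {
    domain_abort("`n_drugs` outside 1-4; no size class defined")
  }
  records |>
    dplyr::mutate(
      ethnicity_fine = scheme$ethnicity_map$ethnicity_broad[m],
      regimen = regimen_size_classes[.data$n_drugs])
}

#' Fine- versus broad-granularity model comparison
#'
#' Trains two models that differ only in categorical granularity (exact
#' ethnicity codes and named regimens versus ONS-style broad ethnicity and
#' regimen size classes), using identical splits and seed, evaluates both on
#' the identical validation records, and reports per-subgroup F2 differences
#' (fine minus broad) alongside the overall difference. Subgroups are keyed
#' on the records' original demographics (broad ethnicity for comparability)
#' so the two reports align row-for-row; the small-group omission rule
#' applies.
#'
#' @param cohort A complete `chemo_cohort`.
#' @param framing A [framing_spec()].
#' @param seed Integer seed shared by the splits and both trainings.
#' @param train_sites,test_fraction Passed to [make_splits()].
#' @param validation `"test"` (held-out patients at training sites) or
#'   `"external"`.
#' @param cv_folds,search_budget Passed to [train_regressor()].
#' @param min_n Subgroup omission threshold.
#' @return An `aggregation_comparison`: list with `fine` and `broad`
#'   subgroup reports, `deltas` (per-subgroup F2 differences), `overall`, and
#'   the two fitted models.
#' @export
compare_fine_vs_broad <- function(cohort, framing, seed = 1L,
                                  train_sites = NULL, test_fraction = 0.2,
                                  validation = "test", cv_folds = 3,
                                  search_budget = 5, min_n = 10) {
  splits <- make_splits(cohort, train_sites = train_sites,
                        test_fraction = test_fraction, seed = seed)
  val_ids <- splits$patient_id[splits$split == validation]
  train_ids <- splits$patient_id[splits$split == "train"]
  eth_map <- ethnicity_reference()

  dims <- c(sex = "sex", ethnicity = "ethnicity_broad", age_decade = "age",
            tumour_type = "tumour_type", regimen = "regimen")

  run_scheme <- function(active) {
    feats <- build_features(cohort, framing, aggregation_scheme(active))
    train <- feats[feats$patient_id %in% train_ids, ]
    attr(train, "feature_cols") <- attr(feats, "feature_cols")
    attr(train, "framing") <- framing
    model <- train_regressor(train, cv_folds = cv_folds,
                             search_budget = search_budget, seed = seed)
    records <- predict_risk(model, feats[feats$patient_id %in% val_ids, ]) |>
      # re-attach the original (fine) demographics so both schemes report on
      # identical subgroup keys
      dplyr::select(-dplyr::any_of(c("ethnicity_fine", "regimen", "n_drugs"))) |>
      dplyr::left_join(
        dplyr::select(cohort$patients, "patient_id", "ethnicity_fine",
                      "regimen", "n_drugs"),
        by = "patient_id") |>
      dplyr::mutate(ethnicity_broad = eth_map$ethnicity_broad[
        match(.data$ethnicity_fine, eth_map$ethnicity_fine)])
    list(model = model,
         records = records,
         report = subgroup_metrics(records, dimensions = dims, min_n = min_n),
         overall_f2 = fbeta(confusion(records$.pred_class, records$truth), 2))
  }

  fine <- run_scheme("fine")
  broad <- run_scheme("broad")
  stopifnot(identical(fine$records$patient_id, broad$records$patient_id))

  deltas <- dplyr::inner_join(
    dplyr::select(fine$report, "dimension", "group", "n_records",
                  f2_fine = "f2"),
    dplyr::select(broad$report, "dimension", "group", f2_broad = "f2"),
    by = c("dimension", "group")) |>
    dplyr::mutate(delta = .data$f2_fine - .data$f2_broad)

  structure(
    list(fine = fine$report, broad = broad$report, deltas = deltas,
         overall = tibble(f2_fine = fine$overall_f2,
                          f2_broad = broad$overall_f2,
                          delta = fine$overall_f2 - broad$overall_f2),
         models = list(fine = fine$model, broad = broad$model)),
    class = "aggregation_comparison")
}

#' @export
print.aggregation_comparison <- function(x, ...) {
  cat(sprintf(
    "<aggregation_comparison> overall F2 fine %.3f vs broad %.3f (delta %+.3f); %d comparable subgroups\n",
    x$overall$f2_fine, x$overall$f2_broad, x$overall$delta, nrow(x$deltas)))
  invisible(x)
}
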