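# Confusion summaries, the F-beta family (F2 primary), threshold sweeps and
# subgroup performance tables with the small-group omission rule.

as_binary_pred <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x > 0.5)
  tolower(as.character(x)) %in% c("high", "event", "1", "true", "yes")
}

#' Confusion summary
#'
#' @param predicted Predicted classes (`"high"`/`"low"`, logical, or 0/1).
#' @param truth True labels (`"event"`/`"no_event"`, logical, or 0/1).
#' @return A one-row `confusion` tibble with `tp`, `fp`, `fn`, `tn`.
#' @export
#' @examples
#' confusion(c("high", "high", "low"), c("event", "no_event", "event"))
confusion <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    domain_abort("`predicted` and `truth` must have equal length")
  }
  p <- as_binary_pred(predicted)
  y <- as_binary_pred(truth)
  structure(tibble(tp = sum(p & y), fp = sum(p & !y),
                   fn = sum(!p & y), tn = sum(!p & !y)),
            class = c("confusion", class(tibble())))
}

#' F-beta score
#'
#' `(1 + beta^2) tp / ((1 + beta^2) tp + fp + beta^2 fn)`; `beta = 2` weights
#' recall four times as much as precision. Defined as 0 when the denominator
#' is 0 (no positives anywhere), a deterministic convention shared by all the
#' package's 0/0 metrics.
#'
#' @param cs A `confusion` row (or any list with `tp`, `fp`, `fn`).
#' @param beta Positive recall weight.
#' @return Scalar in `[0, 1]`.
#' @export
#' @examples
#' fbeta(confusion(rep("high", 10), rep(c("event", "no_event"), c(7, 3))), beta = 2)
fbeta <- function(cs, beta = 2) {
  if (beta <= 0) domain_abort("`beta` must be positive")
  den <- (1 + beta^2) * cs$tp + cs$fp + beta^2 * cs$fn
  ifelse(den == 0, 0, (1 + beta^2) * cs$tp / den)
}

#' @rdname fbeta
#' @return `metric_set()`: one-row tibble with `precision` (positive
#'   predictive value), `recall` (sensitivity), `f1` and `f2`.
#' @export
metric_set <- function(cs) {
  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)
  tibble(precision = safe_div(cs$tp, cs$tp + cs$fp),
         recall = safe_div(cs$tp, cs$tp + cs$fn),
         f1 = fbeta(cs, 1), f2 = fbeta(cs, 2))
}

#' Decision-threshold sweep
#'
#' Re-classifies a fixed set of continuous predictions at each multiplier of
#' the decision rule and reports the resulting confusion counts and metrics.
#' Recall is non-increasing in the multiplier.
#'
#' @param predicted Continuous predicted analyte values.
#' @param baseline Per-record baselines.
#' @param truth True labels as in [confusion()].
#' @param rule A [decision_rule()] template (its multiplier is replaced).
#' @param multipliers Ascending multipliers to evaluate.
#' @param sex Per-record sex for sex-specific ULNs.
#' @return A `threshold_sweep` tibble: one row per multiplier with counts and
#'   `precision`, `recall`, `f1`, `f2`.
#' @export
threshold_sweep <- function(predicted, baseline, truth, rule,
                            multipliers = seq(1, 3, by = 0.1),
                            sex = "female") {
  if (is.unsorted(multipliers)) {
    domain_abort("`multipliers` must be sorted ascending")
  }
  out <- map_dfr(multipliers, function(m) {
    r <- decision_rule(rule$analyte, multiplier = m, uln = rule$uln)
    cls <- classify_risk(predicted, baseline, r, sex = sex)
    cs <- confusion(cls, truth)
    dplyr::bind_cols(tibble(multiplier = m), cs, metric_set(cs))
  })
  class(out) <- c("threshold_sweep", class(tibble()))
  out
}

#' Subgroup performance report
#'
#' Per-record (patient-cycle) metrics within demographic subgroups: a patient
#' receiving five cycles contributes five records to each of their groups.
#' Ages are banded into decades ([age_decade()]). Groups with fewer than
#' `min_n` records are flagged `omitted` and carry no metrics, since metric
#' estimates on so few records are unreliable.
#'
#' @param records Tibble with `.pred_class`, `truth` and the subgroup columns
#'   (e.g. from [predict_risk()] joined with demographics).
#' @param dimensions Named character vector: names are report dimensions,
#'   values are columns of `records` (`age` is banded automatically when the
#'   dimension is `age_decade`).
#' @param min_n Omission threshold (default 10 records).
#' @return A `subgroup_report` tibble: `dimension`, `group`, `n_records`,
#'   `omitted`, confusion counts and metrics (`NA` when omitted).
#' @export
subgroup_metrics <- function(records,
                             dimensions = c(sex = "sex",
                                            ethnicity = "ethnicity_fine",
                                            age_decade = "age",
                                            tumour_type = "tumour_type"),
                             min_n = 10) {
  missing_cols <- setdiff(unname(dimensions), names(records))
  if (length(missing_cols)) {
    domain_abort(sprintf("unknown subgroup dimension column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  out <- map_dfr(names(dimensions), function(dim) {
    col <- dimensions[[dim]]
    key <- if (dim == "age_decade") age_decade(records[[col]]) else
      as.character(records[[col]])
    records |>
      dplyr::mutate(.group = key) |>
      dplyr::group_by(group = .data$.group) |>
      dplyr::group_modify(function(df, g) {
        cs <- confusion(df$.pred_class, df$truth)
        omitted <- nrow(df) < min_n
        met <- if (omitted) {
          tibble(precision = NA_real_, recall = NA_real_,
                 f1 = NA_real_, f2 = NA_real_)
        } else {
          metric_set(cs)
        }
        dplyr::bind_cols(tibble(n_records = nrow(df), omitted = omitted),
                         cs, met)
      }) |>
      dplyr::ungroup() |>
      dplyr::mutate(dimension = dim, .before = 1)
  })
  class(out) <- c("subgroup_report", class(tibble()))
  out
}

#' Per-target-cycle metrics
#'
#' Slices prediction records by target cycle and computes the metric set for
#' each, reproducing the per-cycle performance panels structurally.
#'
#' @param records Output of [predict_risk()].
#' @return Tibble: `target_cycle`, `n_records`, confusion counts and metrics.
#' @export
evaluate_by_cycle <- function(records) {
  records |>
    dplyr::group_by(target_cycle = .data$target_cycle) |>
    dplyr::group_modify(function(df, g) {
      cs <- confusion(df$.pred_class, df$truth)
      dplyr::bind_cols(tibble(n_records = nrow(df)), cs, metric_set(cs))
    }) |>
    dplyr::ungroup()
}
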