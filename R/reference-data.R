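#' Packaged reference tables
#'
#' Three small plain-text reference tables ship with the package:
#'
#' * `cohort_reference_counts()` — per-site summary counts (patients, sex,
#'   tumour types, first grade-change events toward toxicity for creatinine and
#'   bilirubin, age median/range) for the four study-style cohorts that the
#'   default synthetic site profiles emulate.
#' * `ethnicity_reference()` — a fine-grained ethnicity code list with its
#'   many-to-one map to broad ONS-style groups (White, Mixed, Asian, Black,
#'   Other), used by the subgroup-aggregation scheme.
#' * `regimen_reference()` — per tumour type, a small dictionary of first-line
#'   chemotherapy regimens with their drug lists and drug counts (1--4 drugs);
#'   every breast regimen is a doublet so that regimen-size aggregation
#'   collapses all breast treatments into one class.
#'
#' @return A tibble.
#' @name reference_data
NULL

#' @rdname reference_data
#' @export
cohort_reference_counts <- function() {
  readr::read_csv(ctx_file("cohort_reference_counts.csv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname reference_data
#' @export
ethnicity_reference <- function() {
  readr::read_csv(ctx_file("ethnicity_groups.csv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname reference_data
#' @export
regimen_reference <- function() {
  readr::read_csv(ctx_file("regimens.csv"),
                  show_col_types = FALSE, progress = FALSE)
}
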