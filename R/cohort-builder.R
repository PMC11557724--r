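# Inclusion/exclusion rules and the analysis-ready cohort.
#
# Exclusion reasons are assigned in a fixed order (age -> first-line ->
# one-cycle -> cycle-gap -> missing bloods) so every dropped patient gets
# exactly one primary reason and the exclusion log is deterministic.

#' Apply inclusion and exclusion criteria
#'
#' Retains adult (>= 18) first-line patients who received at least two
#' treatment cycles with the second no more than 60 days after the first
#' (a gap of exactly 60 days is retained; only gaps strictly greater than 60
#' exclude). Dropped patients are recorded in an exclusion log with one
#' primary reason each (`age`, `not_first_line`, `one_cycle`, `cycle_gap`).
#'
#' @param cohort A `chemo_cohort` (or list with `patients`/`observations`).
#' @return The filtered `chemo_cohort` with an `exclusions` tibble
#'   (`patient_id`, `reason`) appended.
#' @export
apply_inclusion_criteria <- function(cohort) {
  patients <- cohort$patients
  obs <- cohort$observations
  if (anyDuplicated(patients$patient_id)) {
    domain_abort("`patients$patient_id` must be unique")
  }
  if (!"first_line" %in% names(patients)) patients$first_line <- TRUE

  treat <- obs |>
    dplyr::filter(.data$cycle >= 1) |>
    dplyr::arrange(.data$patient_id, .data$cycle) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      n_cycles = dplyr::n(),
      gap = if (dplyr::n() >= 2) .data$day_offset[2] - .data$day_offset[1] else NA_real_,
      .groups = "drop")

  info <- patients |>
    dplyr::left_join(treat, by = "patient_id") |>
    dplyr::mutate(
      reason = dplyr::case_when(
        .data$age < 18 ~ "age",
        !dplyr::coalesce(.data$first_line, TRUE) ~ "not_first_line",
        is.na(.data$n_cycles) | .data$n_cycles < 2 ~ "one_cycle",
        .data$gap > 60 ~ "cycle_gap",
        TRUE ~ NA_character_))
  exclusions <- info |>
    dplyr::filter(!is.na(.data$reason)) |>
    dplyr::select("patient_id", "reason")

  keep <- setdiff(patients$patient_id, exclusions$patient_id)
  out <- structure(
    list(patients = dplyr::filter(patients, .data$patient_id %in% keep),
         observations = dplyr::filter(obs, .data$patient_id %in% keep),
         events = if (!is.null(cohort$events)) {
           dplyr::filter(cohort$events, .data$patient_id %in% keep)
         },
         exclusions = dplyr::bind_rows(cohort$exclusions, exclusions)),
    class = "chemo_cohort")
  attr(out, "config") <- attr(cohort, "config")
  out
}

#' Remove patients with missing blood test data
#'
#' Drops any patient missing one or more of the five analytes at baseline or
#' any of cycles 1--6 (or missing a cycle row entirely). Missing demographic
#' data (comorbidities, height, weight, dose intensity, unknown ethnicity) are
#' allowed and retained with their missingness intact.
#'
#' @param cohort A `chemo_cohort`, normally after [apply_inclusion_criteria()].
#' @return The complete-case `chemo_cohort`; dropped patients are appended to
#'   the exclusion log with reason `missing_bloods`.
#' @export
remove_missing_bloods <- function(cohort) {
  obs <- cohort$observations
  complete <- obs |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      ok = dplyr::n() == 7 && setequal(.data$cycle, 0:6) &&
        !anyNA(dplyr::pick(dplyr::all_of(analytes()))),
      .groups = "drop")
  drop <- dplyr::filter(complete, !.data$ok)$patient_id
  drop <- union(drop, setdiff(cohort$patients$patient_id, complete$patient_id))
  keep <- setdiff(cohort$patients$patient_id, drop)
  out <- structure(
    list(patients = dplyr::filter(cohort$patients, .data$patient_id %in% keep),
         observations = dplyr::filter(obs, .data$patient_id %in% keep),
         events = if (!is.null(cohort$events)) {
           dplyr::filter(cohort$events, .data$patient_id %in% keep)
         },
         exclusions = dplyr::bind_rows(
           cohort$exclusions,
           tibble(patient_id = drop, reason = "missing_bloods"))),
    class = "chemo_cohort")
  attr(out, "config") <- attr(cohort, "config")
  out
}

#' @rdname apply_inclusion_criteria
#' @details `build_cohort()` chains [apply_inclusion_criteria()] and
#'   [remove_missing_bloods()].
#' @export
build_cohort <- function(cohort) {
  remove_missing_bloods(apply_inclusion_criteria(cohort))
}

#' Per-site cohort summary table
#'
#' Counts and percentages per site: patients, age median/range, sex, tumour
#' types and — when labels are supplied — patients with a first grade-change
#' toward toxicity per analyte. Percentages use the site's post-exclusion
#' patient count as denominator, and are rounded to the conventional printed
#' precision: one decimal for sex and tumour type, nearest integer for grade
#' changes.
#'
#' @param patients A patients tibble or a `chemo_cohort`.
#' @param labels Optional label tibble from [derive_labels()].
#' @return A long tibble: `site`, `statistic`, `value` (counts or years) and
#'   `percent` (`NA` where a percentage is not meaningful).
#' @export
#' @examples
#' pts <- tibble::tibble(patient_id = as.character(1:10), site = "a",
#'                       age = c(40, 45, 50, 55, 60, 62, 64, 66, 68, 70),
#'                       sex = rep(c("female", "male"), 5),
#'                       tumour_type = rep(c("breast", "bowel"), 5))
#' summarize_cohort(pts)
summarize_cohort <- function(patients, labels = NULL) {
  if (inherits(patients, "chemo_cohort")) patients <- patients$patients
  if (nrow(patients) == 0) {
    return(tibble(site = character(), statistic = character(),
                  value = numeric(), percent = numeric()))
  }
  tumours <- c("breast", "bowel", "dlbcl", "lung", "ovarian")
  per_site <- function(df) {
    n <- nrow(df)
    sex_n <- vapply(c("female", "male"), function(s) sum(df$sex == s), 0)
    tum_n <- vapply(tumours, function(t) sum(df$tumour_type == t), 0)
    rows <- dplyr::bind_rows(
      tibble(statistic = c("n_patients", "age_median", "age_min", "age_max"),
             value = c(n, median(df$age), min(df$age), max(df$age)),
             percent = NA_real_),
      tibble(statistic = paste0("sex_", names(sex_n)), value = unname(sex_n),
             percent = unname(round(100 * sex_n / n, 1))),
      tibble(statistic = paste0("tumour_", names(tum_n)), value = unname(tum_n),
             percent = unname(round(100 * tum_n / n, 1))))
    if (!is.null(labels)) {
      ev <- labels |>
        dplyr::filter(.data$patient_id %in% df$patient_id, .data$event) |>
        dplyr::count(.data$analyte)
      ev_n <- vapply(graded_analytes(),
                     function(a) sum(ev$n[ev$analyte == a]), 0)
      rows <- dplyr::bind_rows(
        rows,
        tibble(statistic = paste0(names(ev_n), "_grade_changes"),
               value = unname(ev_n), percent = unname(round(100 * ev_n / n))))
    }
    rows
  }
  patients |>
    dplyr::group_by(site = .data$site) |>
    dplyr::group_modify(~ per_site(.x)) |>
    dplyr::ungroup()
}
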