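# CTCAE-style grade ladders, grade-change-toward-toxicity labelling, and the
# sensitivity-tuned 1.4x decision boundaries that turn predicted lab values
# into high/low-risk classes.

#' Default upper limits of normal
#'
#' Configurable defaults: creatinine 104 umol/L (male) / 90 umol/L (female);
#' bilirubin 21 umol/L (sex-independent).
#'
#' @param analyte `"creatinine"` or `"bilirubin"`.
#' @param sex Character vector (`"female"`/`"male"`); recycled for bilirubin.
#' @return Numeric vector of ULNs in umol/L.
#' @export
default_uln <- function(analyte, sex) {
  analyte <- match.arg(analyte, graded_analytes())
  if (analyte == "creatinine") ifelse(sex == "male", 104, 90)
  else rep(21, length(sex))
}

#' CTCAE-style grade ladder
#'
#' Grade thresholds for a graded analyte. For creatinine the grade-1 rung is
#' `max(1.5 x baseline, 1.5 x ULN)` with higher rungs at `3 x ULN` and
#' `6 x ULN`; for bilirubin the rungs are `1.5 x ULN`, `3 x ULN` and
#' `10 x ULN`. A value's grade is the highest rung it strictly exceeds
#' (0 below all rungs). Rungs are made cumulative (non-decreasing) so grading
#' stays monotone even for patients with a grossly elevated baseline.
#'
#' @param analyte `"creatinine"` or `"bilirubin"`.
#' @param uln Upper limit of normal in umol/L (scalar or per-observation).
#' @param uln_multipliers Strictly increasing rung multipliers applied to ULN.
#' @param baseline_factor Multiplier applied to baseline in the grade-1 rung
#'   (creatinine only; `NA` disables the baseline-relative arm).
#' @return A `grade_ladder` object.
#' @export
grade_ladder <- function(analyte,
                         uln = NULL,
                         uln_multipliers = NULL,
                         baseline_factor = NULL) {
  analyte <- match.arg(analyte, graded_analytes())
  uln_multipliers <- uln_multipliers %||%
    if (analyte == "creatinine") c(1.5, 3, 6) else c(1.5, 3, 10)
  if (any(diff(uln_multipliers) <= 0)) {
    config_abort("uln_multipliers", "must be strictly increasing")
  }
  baseline_factor <- baseline_factor %||%
    if (analyte == "creatinine") 1.5 else NA_real_
  if (!is.null(uln) && any(uln <= 0)) config_abort("uln", "must be > 0")
  structure(list(analyte = analyte, uln = uln,
                 uln_multipliers = uln_multipliers,
                 baseline_factor = baseline_factor),
            class = "grade_ladder")
}

ladder_uln <- function(ladder, sex) {
  ladder$uln %||% default_uln(ladder$analyte, sex)
}

#' Grade a lab value on a ladder
#'
#' @param value,baseline Positive lab values in analyte units; vectorised.
#' @param ladder A [grade_ladder()].
#' @param sex Used only to resolve a sex-specific default ULN when the ladder
#'   does not fix one.
#' @return Integer grades (0 = below every rung).
#' @export
#' @examples
#' grade(170, 100, grade_ladder("creatinine", uln = 104)) # grade 1
#' grade(70, 8, grade_ladder("bilirubin", uln = 21))      # grade 2
grade <- function(value, baseline, ladder, sex = "female") {
  stopifnot(inherits(ladder, "grade_ladder"))
  if (any(!is.finite(value) | value <= 0) || any(!is.finite(baseline) | baseline <= 0)) {
    domain_abort("`value` and `baseline` must be positive and finite")
  }
  uln <- ladder_uln(ladder, sex)
  n <- max(length(value), length(baseline), length(uln))
  value <- rep_len(value, n); baseline <- rep_len(baseline, n)
  uln <- rep_len(uln, n)
  g <- integer(n)
  prev <- rep(-Inf, n)
  for (k in seq_along(ladder$uln_multipliers)) {
    rung <- ladder$uln_multipliers[k] * uln
    if (k == 1 && is.finite(ladder$baseline_factor)) {
      rung <- pmax(rung, ladder$baseline_factor * baseline)
    }
    rung <- pmax(rung, prev) # keep rungs non-decreasing
    g <- g + (value > rung)
    prev <- rung
  }
  g
}

#' Label grade changes toward toxicity
#'
#' Scans each patient's complete baseline-plus-six-cycle trajectory for each
#' graded analyte and records at most one event: the first treatment cycle
#' whose grade strictly exceeds the lowest grade seen at any earlier cycle
#' (including baseline). Grade improvements never produce events, and a
#' patient who worsens, recovers and worsens again is still recorded once, at
#' the first worsening.
#'
#' @param cohort A `chemo_cohort`, or a list with `patients` and
#'   `observations` tibbles. Trajectories must be complete (cycles 0--6, no
#'   missing creatinine/bilirubin); run [remove_missing_bloods()] first.
#' @param ladders Named list of [grade_ladder()]s (defaults per analyte).
#' @return Tibble with one row per patient x analyte: `patient_id`, `analyte`,
#'   `event`, `first_change_cycle` (`NA` when no event) and grades `grade_0`
#'   ... `grade_6`.
#' @export
derive_labels <- function(cohort, ladders = NULL) {
  patients <- cohort$patients
  obs <- cohort$observations
  ladders <- ladders %||% list(creatinine = grade_ladder("creatinine"),
                               bilirubin = grade_ladder("bilirubin"))
  obs <- dplyr::arrange(obs, .data$patient_id, .data$cycle)
  counts <- dplyr::count(obs, .data$patient_id)
  if (any(counts$n != 7)) {
    domain_abort(sprintf(
      "incomplete trajectories (expected cycles 0-6) for %d patient(s), e.g. %s",
      sum(counts$n != 7), counts$patient_id[counts$n != 7][1]))
  }
  sex <- patients$sex[match(unique(obs$patient_id), patients$patient_id)]
  dplyr::bind_rows(lapply(graded_analytes(), function(a) {
    if (any(is.na(obs[[a]]))) {
      domain_abort(sprintf("missing %s values; remove incomplete patients first", a))
    }
    vals <- matrix(obs[[a]], ncol = 7, byrow = TRUE)
    g <- matrix(grade(as.vector(vals), rep(vals[, 1], 7), ladders[[a]],
                      sex = rep(sex, 7)), ncol = 7)
    first_change <- apply(g, 1, function(gr) {
      run_min <- cummin(gr)
      idx <- which(gr[-1] > run_min[-7])
      if (length(idx)) idx[1] else NA_integer_
    })
    out <- tibble(patient_id = unique(obs$patient_id), analyte = a,
                  event = !is.na(first_change),
                  first_change_cycle = as.integer(first_change))
    gr <- as_tibble(as.data.frame(g))
    names(gr) <- paste0("grade_", 0:6)
    dplyr::bind_cols(out, gr)
  }))
}

#' Sensitivity-tuned decision threshold rule
#'
#' Converts a predicted analyte value into a high/low-risk class. The default
#' multiplier of 1.4 is deliberately tighter than the 1.5x grade-1 ladder
#' rung: lowering the multiplier can only flag more patients, so sensitivity
#' never decreases. For creatinine a prediction is high risk when it reaches
#' `1.4 x baseline` **or** `1.4 x ULN` — an effective threshold of
#' `min(1.4 x baseline, 1.4 x ULN)`; for bilirubin the boundary is
#' `1.4 x ULN`. The boundary is inclusive (`>=`).
#'
#' @param analyte `"creatinine"` or `"bilirubin"`.
#' @param multiplier Dimensionless threshold multiplier (> 1 by default
#'   convention; any positive value is accepted for threshold sweeps).
#' @param uln Optional fixed ULN; default resolves per sex.
#' @return A `decision_rule` object.
#' @export
decision_rule <- function(analyte, multiplier = 1.4, uln = NULL) {
  analyte <- match.arg(analyte, graded_analytes())
  if (!is.numeric(multiplier) || multiplier <= 0) {
    config_abort("multiplier", "must be positive")
  }
  structure(list(analyte = analyte, multiplier = multiplier, uln = uln),
            class = "decision_rule")
}

#' @rdname decision_rule
#' @param baseline Baseline analyte value(s).
#' @param sex Sex vector used for sex-specific default ULNs.
#' @return `risk_threshold()`: the numeric decision threshold per observation.
#' @export
risk_threshold <- function(rule, baseline, sex = "female") {
  stopifnot(inherits(rule, "decision_rule"))
  uln <- rule$uln %||% default_uln(rule$analyte, sex)
  if (rule$analyte == "creatinine") {
    pmin(rule$multiplier * baseline, rule$multiplier * uln)
  } else {
    rep_len(rule$multiplier * uln, max(length(baseline), length(uln)))
  }
}

#' @rdname decision_rule
#' @param predicted Predicted analyte value(s), finite.
#' @param rule A `decision_rule`.
#' @return `classify_risk()`: character vector `"high"`/`"low"`.
#' @export
#' @examples
#' classify_risk(120, 80, decision_rule("creatinine", uln = 104)) # "high"
classify_risk <- function(predicted, baseline, rule, sex = "female") {
  if (any(!is.finite(predicted))) domain_abort("`predicted` must be finite")
  thr <- risk_threshold(rule, baseline, sex)
  ifelse(predicted >= thr, "high", "low")
}
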