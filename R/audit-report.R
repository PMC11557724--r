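# Machine-readable bias-mitigation audit report.

#' Assemble a six-section bias audit report
#'
#' Packages the outputs of a full analysis into a machine-readable report
#' mirroring a six-step bias-mitigation checklist for multi-site clinical ML:
#'
#' 1. `multi_site_statistics` — classical per-site summary statistics
#'    ([summarize_cohort()]).
#' 2. `site_distribution_comparison` — per-feature cross-site distribution
#'    comparison ([compare_distributions()]).
#' 3. `per_site_holdout_metrics` — performance metrics on each site's
#'    held-out / external data.
#' 4. `formal_fairness_measures` — GEI and between-group GEI
#'    ([gei_threshold_curve()] output or a summary of it).
#' 5. `deployment_restrictions` — populations where performance falls below
#'    an acceptable floor ([deployment_flags()]).
#' 6. `aggregation_effects` — effect of categorical coarsening on subgroup
#'    performance (the `deltas`/`overall` of [compare_fine_vs_broad()]).
#'
#' @param multi_site_statistics,site_distribution_comparison,per_site_holdout_metrics,formal_fairness_measures,deployment_restrictions,aggregation_effects
#'   Data frames (or JSON-serialisable lists) for each section.
#' @return A `bias_audit` list with exactly these six sections.
#' @export
bias_audit <- function(multi_site_statistics,
                       site_distribution_comparison,
                       per_site_holdout_metrics,
                       formal_fairness_measures,
                       deployment_restrictions,
                       aggregation_effects) {
  structure(
    list(multi_site_statistics = multi_site_statistics,
         site_distribution_comparison = site_distribution_comparison,
         per_site_holdout_metrics = per_site_holdout_metrics,
         formal_fairness_measures = formal_fairness_measures,
         deployment_restrictions = deployment_restrictions,
         aggregation_effects = aggregation_effects),
    class = "bias_audit")
}

#' @rdname bias_audit
#' @param site_metrics Tibble with at least `site` and `f2` columns.
#' @param f2_floor Sites/subgroups with F2 below this floor are flagged for
#'   deployment restriction.
#' @export
deployment_flags <- function(site_metrics, f2_floor = 0.5) {
  site_metrics |>
    dplyr::mutate(restrict = .data$f2 < f2_floor,
                  f2_floor = f2_floor)
}

#' @rdname bias_audit
#' @param report A `bias_audit`.
#' @param path Output JSON path.
#' @export
write_bias_audit <- function(report, path) {
  stopifnot(inherits(report, "bias_audit"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
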