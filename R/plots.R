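# ggplot2 displays for the package's result types.

#' Plot methods
#'
#' `autoplot()` methods for the package's tabular results:
#' * `threshold_sweep` — precision/recall/F2 against the decision multiplier;
#' * `subgroup_report` — per-subgroup F2 bars annotated with record counts
#'   (omitted small groups are not plotted), faceted by dimension;
#' * `gei_curve` — individual and between-group GEI against sensitivity (a
#'   perfect model is the single point at GEI 0, sensitivity 1);
#' * `shift_comparison` — |SMD| / TVD per feature and site pair, with the
#'   flagging threshold drawn.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot.
#' @name chemotox-autoplot
NULL

#' @rdname chemotox-autoplot
#' @export
autoplot.threshold_sweep <- function(object, ...) {
  object |>
    tidyr::pivot_longer(c("precision", "recall", "f2"),
                        names_to = "metric", values_to = "value") |>
    ggplot(aes(x = .data$multiplier, y = .data$value,
               colour = .data$metric)) +
    geom_line() +
    geom_point(size = 1) +
    labs(x = "decision threshold multiplier", y = NULL, colour = NULL) +
    theme_minimal()
}

#' @rdname chemotox-autoplot
#' @export
autoplot.subgroup_report <- function(object, ...) {
  object |>
    dplyr::filter(!.data$omitted) |>
    ggplot(aes(x = .data$group, y = .data$f2)) +
    geom_col(fill = "steelblue") +
    geom_text(aes(label = .data$n_records), vjust = -0.3, size = 3) +
    facet_wrap(~dimension, scales = "free_x") +
    labs(x = NULL, y = "F2") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' @rdname chemotox-autoplot
#' @export
autoplot.gei_curve <- function(object, ...) {
  object |>
    tidyr::pivot_longer(c("gei", "between_group"),
                        names_to = "index", values_to = "value") |>
    ggplot(aes(x = .data$sensitivity, y = .data$value,
               colour = .data$index)) +
    geom_path() +
    geom_point(size = 1) +
    labs(x = "sensitivity", y = "Generalised Entropy Index", colour = NULL) +
    theme_minimal()
}

#' @rdname chemotox-autoplot
#' @export
autoplot.shift_comparison <- function(object, ...) {
  thr <- attr(object, "smd_threshold") %||% 0.1
  object |>
    dplyr::mutate(
      statistic = dplyr::coalesce(abs(.data$smd), .data$tvd),
      pair = paste(.data$site_a, "vs", .data$site_b)) |>
    ggplot(aes(x = .data$statistic, y = .data$feature,
               colour = .data$flagged)) +
    geom_point() +
    geom_vline(xintercept = thr, linetype = "dashed") +
    facet_wrap(~pair) +
    labs(x = "|SMD| (numeric) / TVD (categorical)", y = NULL) +
    theme_minimal()
}

#' Per-cycle F2 plot
#'
#' @param by_cycle Output of [evaluate_by_cycle()], optionally row-bound
#'   across models with a `model` column.
#' @return A ggplot of F2 against target cycle.
#' @export
plot_f2_by_cycle <- function(by_cycle) {
  p <- ggplot(by_cycle, aes(x = .data$target_cycle, y = .data$f2))
  if ("model" %in% names(by_cycle)) {
    p <- p + geom_line(aes(colour = .data$model)) +
      geom_point(aes(colour = .data$model))
  } else {
    p <- p + geom_line() + geom_point()
  }
  p + labs(x = "target cycle", y = "F2") + theme_minimal()
}
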