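# broom-style tidiers for fitted objects.

#' Tidy a fitted risk model
#'
#' `tidy()` returns the hyperparameter-search trials (one row per trial with
#' its cross-validated RMSE); `glance()` returns a one-row summary of the
#' chosen configuration.
#'
#' @param x A `risk_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.risk_model <- function(x, ...) {
  x$trials |>
    dplyr::mutate(trial = dplyr::row_number(), .before = 1) |>
    dplyr::mutate(chosen = .data$cv_rmse == min(.data$cv_rmse))
}

#' @rdname tidy.risk_model
#' @export
glance.risk_model <- function(x, ...) {
  tibble(analyte = x$analyte, mode = x$mode, n_train = x$n_train,
         n_features = length(x$feature_cols), cv_folds = x$cv_folds,
         n_trials = nrow(x$trials), max_depth = x$best$max_depth,
         eta = x$best$eta, nrounds = x$best$nrounds,
         subsample = x$best$subsample, cv_rmse = x$best$cv_rmse,
         seed = x$seed)
}

#' @rdname tidy.risk_model
#' @details `tidy()` on an `aggregation_comparison` returns the per-subgroup
#'   F2 deltas; `glance()` the overall F2 pair.
#' @export
tidy.aggregation_comparison <- function(x, ...) x$deltas

#' @rdname tidy.risk_model
#' @export
glance.aggregation_comparison <- function(x, ...) x$overall
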