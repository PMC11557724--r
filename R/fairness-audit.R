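# Benefit formulation and the Generalised Entropy Index (GEI), individual and
# between-group, with threshold sweeps.

#' Per-record benefit
#'
#' `b = M(x) - y + 1` with prediction `M` and label `y` in `{0, 1}`: false
#' negatives receive benefit 0 (highest penalty), false positives 2 (lowest),
#' correct calls 1.
#'
#' @param predicted Predicted classes as in [confusion()].
#' @param truth True labels as in [confusion()].
#' @return Integer vector of benefits in `{0, 1, 2}`.
#' @export
#' @examples
#' compute_benefits(c("high", "low", "low"), c("no_event", "event", "no_event"))
compute_benefits <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    domain_abort("`predicted` and `truth` must have equal length")
  }
  as.integer(as_binary_pred(predicted)) - as.integer(as_binary_pred(truth)) + 1L
}

check_gei_inputs <- function(b, alpha) {
  if (!length(b)) domain_abort("benefit vector is empty")
  if (alpha %in% c(0, 1)) {
    domain_abort("`alpha` must not be 0 or 1 for this form of the index")
  }
  mu <- mean(b)
  if (mu <= 0) {
    abort("mean benefit is 0 (all-false-negative set); GEI is undefined here",
          class = "chemotox_degenerate_error")
  }
  mu
}

#' Generalised Entropy Index
#'
#' Individual-level inequality of the benefit distribution,
#' `I^alpha(b) = 1 / (n alpha (alpha - 1)) * sum_i ((b_i / mu)^alpha - 1)`,
#' with `mu` the mean benefit. Zero iff all benefits are equal; invariant to
#' record order and to replicating every record. `alpha = 2` (the default) is
#' the form used in the package's reports.
#'
#' @param b Benefit vector (see [compute_benefits()]).
#' @param alpha Exponent, not 0 or 1.
#' @return Non-negative scalar.
#' @export
#' @examples
#' gei(c(0, 2))       # 0.5
#' gei(c(1, 1, 0, 2)) # 0.25
gei <- function(b, alpha = 2) {
  mu <- check_gei_inputs(b, alpha)
  sum((b / mu)^alpha - 1) / (length(b) * alpha * (alpha - 1))
}

#' Between-group Generalised Entropy Index
#'
#' `I^alpha_beta(b) = sum_g n_g / (n alpha (alpha - 1)) ((mu_g / mu)^alpha - 1)`
#' over a disjoint, exhaustive grouping of the records. Zero whenever every
#' group's mean benefit equals the overall mean; for `alpha = 2` it is the
#' between-group term of the decomposition
#' `I^2(b) = I^2_beta(b) + sum_g (n_g / n) (mu_g / mu)^2 I^2(b_g)`.
#' Values are reported exactly as the formula yields them (they can be
#' negative in exotic cases) — no clamping.
#'
#' @param b Benefit vector.
#' @param groups Group membership vector, same length as `b`.
#' @param alpha Exponent, not 0 or 1.
#' @return Scalar.
#' @export
#' @examples
#' between_group_gei(c(0, 0, 2, 2), c("a", "a", "b", "b")) # 0.5
between_group_gei <- function(b, groups, alpha = 2) {
  if (length(groups) != length(b)) {
    domain_abort("`groups` must align with `b`")
  }
  mu <- check_gei_inputs(b, alpha)
  groups <- as.character(groups)
  if (anyNA(groups)) config_abort("groups", "must not contain missing values")
  n <- length(b)
  split_b <- split(b, groups)
  if (any(lengths(split_b) == 0)) config_abort("groups", "contains an empty group")
  sum(vapply(split_b, function(bg) {
    length(bg) / (n * alpha * (alpha - 1)) * ((mean(bg) / mu)^alpha - 1)
  }, 0))
}

#' GEI across decision thresholds
#'
#' Reclassifies continuous predictions at each multiplier of the decision
#' rule and pairs the resulting sensitivity with the individual and
#' between-group GEI at that threshold. A perfect classifier at some
#' threshold yields the point (GEI 0, sensitivity 1). Thresholds at which
#' every record is a false negative (mean benefit 0) are dropped from the
#' curve with a message.
#'
#' @param predicted Continuous predicted analyte values.
#' @param baseline Per-record baselines.
#' @param truth True labels.
#' @param groups Group membership vector for the between-group index.
#' @param rule A [decision_rule()] template.
#' @param multipliers Ascending multipliers to evaluate.
#' @param alpha GEI exponent.
#' @param sex Per-record sex for sex-specific ULNs.
#' @return A `gei_curve` tibble: `multiplier`, `sensitivity`, `gei`,
#'   `between_group`, `n`.
#' @export
gei_threshold_curve <- function(predicted, baseline, truth, groups, rule,
                                multipliers = seq(1, 3, by = 0.1),
                                alpha = 2, sex = "female") {
  if (is.unsorted(multipliers)) {
    domain_abort("`multipliers` must be sorted ascending")
  }
  out <- map_dfr(multipliers, function(m) {
    r <- decision_rule(rule$analyte, multiplier = m, uln = rule$uln)
    cls <- classify_risk(predicted, baseline, r, sex = sex)
    b <- compute_benefits(cls, truth)
    if (mean(b) <= 0) {
      inform(sprintf(
        "multiplier %.3g dropped from GEI curve: all records false negative", m))
      return(tibble())
    }
    cs <- confusion(cls, truth)
    tibble(multiplier = m, sensitivity = metric_set(cs)$recall,
           gei = gei(b, alpha),
           between_group = between_group_gei(b, groups, alpha),
           n = length(b))
  })
  class(out) <- c("gei_curve", class(tibble()))
  out
}
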