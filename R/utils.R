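# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so package functions never disturb the session stream.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Configuration error with the offending field named, per the generator contract.
config_abort <- function(field, msg) {
  abort(sprintf("Invalid configuration: field `%s` %s", field, msg),
        class = "chemotox_config_error")
}

domain_abort <- function(msg) {
  abort(msg, class = "chemotox_domain_error")
}

check_prob <- function(x, field) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    config_abort(field, "must contain probabilities in [0, 1]")
  }
  invisible(x)
}

check_mix <- function(x, field, tol = 1e-9) {
  check_prob(x, field)
  if (abs(sum(x) - 1) > tol) {
    config_abort(field, sprintf("must sum to 1 (got %.12f)", sum(x)))
  }
  invisible(x)
}

# Truncated-normal draw by rejection; adequate for the mild truncations used here.
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out < lower | out > upper)
  }
  out
}

#' Assign ages to decade bands
#'
#' Ages are banded into decades for subgroup reporting; adults aged 18--19 fall
#' in the "10-19" band and ages of 90 or more are pooled into "90+".
#'
#' @param age Numeric vector of ages in years.
#' @return Character vector of decade labels, e.g. `"50-59"`.
#' @export
#' @examples
#' age_decade(c(18, 42, 90))
age_decade <- function(age) {
  if (any(!is.finite(age) & !is.na(age))) domain_abort("`age` must be finite")
  lo <- pmin(floor(age / 10) * 10, 90)
  ifelse(is.na(age), NA_character_,
         ifelse(lo >= 90, "90+", sprintf("%d-%d", lo, lo + 9)))
}

analytes <- function() c("creatinine", "bilirubin", "haemoglobin", "anc", "alt")
graded_analytes <- function() c("creatinine", "bilirubin")

ctx_file <- function(...) {
  system.file("extdata", ..., package = "chemotox", mustWork = TRUE)
}
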