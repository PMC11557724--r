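# Multi-site synthetic cohort generator.
#
# Emulates the statistical structure of multi-hospital chemotherapy extracts:
# per-site demographic and tumour mixes, site-shifted baseline laboratory
# distributions, per-analyte grade-change (toxicity) event rates over cycles
# 3-6, cycle-dependent blood-panel missingness and a temporally drifted cohort.
# Laboratory units: creatinine and bilirubin in umol/L, haemoglobin in g/L,
# absolute neutrophil count (ANC) in 10^9/L, ALT in U/L.

#' Describe one synthetic site
#'
#' A site profile holds the population-level quantities the generator draws
#' from for one hospital: cohort size, age distribution (median/range/spread),
#' sex and ethnicity and tumour mixes, per-analyte baseline lab parameters with
#' an additive site shift for baseline creatinine, per-analyte probabilities of
#' a grade-change event over cycles 3--6, a per-cycle blood-panel missingness
#' curve and a multiplicative temporal drift applied to lab means.
#'
#' @param site_id Site identifier string.
#' @param n_patients Number of patients to simulate (>= 1).
#' @param age Numeric vector `c(median, min, max, sd)` in years.
#' @param sex_female Proportion of female patients, in `[0, 1]`.
#' @param ethnicity_mix Named probability vector over fine-grained ethnicity
#'   codes (see [ethnicity_reference()]); must sum to 1.
#' @param tumour_mix Named probability vector over
#'   `breast, bowel, dlbcl, lung, ovarian`; must sum to 1.
#' @param baseline_labs Named list of `c(mean, sd)` per analyte, in analyte
#'   units (creatinine/bilirubin umol/L, haemoglobin g/L, ANC 10^9/L, ALT U/L).
#' @param creatinine_shift Additive shift (umol/L) applied to the site's mean
#'   baseline creatinine; models cross-site assay/population differences.
#' @param toxicity_rates Named vector `c(creatinine = p, bilirubin = p)` of
#'   per-patient probabilities of a grade-change event during cycles 3--6.
#' @param missingness Length-7 per-cycle (0--6) probability that a cycle's
#'   whole blood panel is missing; must be monotone non-decreasing and the
#'   baseline entry is never applied.
#' @param temporal_shift Multiplicative drift on all lab means (1 = none).
#' @return A `site_profile` object (a validated list).
#' @export
site_profile <- function(site_id,
                         n_patients,
                         age = c(60, 18, 90, 13),
                         sex_female = 0.6,
                         ethnicity_mix = default_ethnicity_mix(),
                         tumour_mix = c(breast = 0.35, bowel = 0.4, dlbcl = 0.25,
                                        lung = 0, ovarian = 0),
                         baseline_labs = default_baseline_labs(),
                         creatinine_shift = 0,
                         toxicity_rates = c(creatinine = 0.1, bilirubin = 0.1),
                         missingness = rep(0, 7),
                         temporal_shift = 1) {
  if (!is.numeric(n_patients) || n_patients < 1) {
    config_abort("n_patients", "must be >= 1")
  }
  if (length(age) != 4 || age[2] > age[1] || age[1] > age[3] || age[4] <= 0) {
    config_abort("age", "must be c(median, min, max, sd) with min <= median <= max, sd > 0")
  }
  check_prob(sex_female, "sex_female")
  check_mix(ethnicity_mix, "ethnicity_mix")
  known <- ethnicity_reference()$ethnicity_fine
  if (!all(names(ethnicity_mix) %in% known)) {
    config_abort("ethnicity_mix", sprintf(
      "contains codes outside the reference list: %s",
      paste(setdiff(names(ethnicity_mix), known), collapse = ", ")))
  }
  check_mix(tumour_mix, "tumour_mix")
  if (!setequal(names(tumour_mix),
                c("breast", "bowel", "dlbcl", "lung", "ovarian"))) {
    config_abort("tumour_mix", "must be named over breast, bowel, dlbcl, lung, ovarian")
  }
  if (!setequal(names(baseline_labs), analytes())) {
    config_abort("baseline_labs", "must name all five analytes")
  }
  for (a in analytes()) {
    p <- baseline_labs[[a]]
    if (length(p) != 2 || p[1] <= 0 || p[2] <= 0) {
      config_abort(paste0("baseline_labs$", a), "must be c(mean, sd) with both > 0")
    }
  }
  if (!setequal(names(toxicity_rates), graded_analytes())) {
    config_abort("toxicity_rates", "must be named over creatinine, bilirubin")
  }
  check_prob(toxicity_rates, "toxicity_rates")
  check_missingness_curve(missingness)
  if (!is.numeric(temporal_shift) || temporal_shift <= 0) {
    config_abort("temporal_shift", "must be > 0")
  }
  structure(
    list(site_id = as.character(site_id), n_patients = as.integer(n_patients),
         age = as.numeric(age), sex_female = sex_female,
         ethnicity_mix = ethnicity_mix, tumour_mix = tumour_mix,
         baseline_labs = baseline_labs, creatinine_shift = creatinine_shift,
         toxicity_rates = toxicity_rates, missingness = missingness,
         temporal_shift = temporal_shift),
    class = "site_profile")
}

check_missingness_curve <- function(curve) {
  if (length(curve) != 7) config_abort("missingness", "must have 7 entries (cycles 0-6)")
  check_prob(curve, "missingness")
  if (any(diff(curve) < 0)) {
    config_abort("missingness", "must be monotone non-decreasing in cycle")
  }
  invisible(curve)
}

#' @rdname site_profile
#' @export
default_ethnicity_mix <- function() {
  mix <- c("Irish" = 0.03, "Any other White background" = 0.08,
           "White and Black Caribbean" = 0.01, "White and Black African" = 0.01,
           "White and Asian" = 0.01, "Any other Mixed background" = 0.01,
           "Indian" = 0.05, "Pakistani" = 0.03, "Bangladeshi" = 0.01,
           "Chinese" = 0.01, "Any other Asian background" = 0.02,
           "African" = 0.04, "Caribbean" = 0.03,
           "Any other Black background" = 0.01,
           "Arab" = 0.01, "Any other ethnic group" = 0.02, "Unknown" = 0.02)
  c("British" = 1 - sum(mix), mix)
}

#' @rdname site_profile
#' @export
default_baseline_labs <- function() {
  list(creatinine = c(72, 13), bilirubin = c(9, 3), haemoglobin = c(133, 12),
       anc = c(4.5, 1.3), alt = c(22, 9))
}

#' Default four-site study profiles
#'
#' Site profiles whose population quantities (cohort sizes, age medians and
#' ranges, sex and tumour mixes, grade-change event rates) follow the packaged
#' per-site reference counts ([cohort_reference_counts()]): three contemporary
#' hospitals plus a temporally shifted later extract from the first hospital
#' that adds lung and ovarian tumours absent from the others. Event rates are
#' `events / n_patients` from the reference counts. Baseline creatinine means
#' carry distinct per-site additive shifts so that cross-site shift detection
#' has a real signal to find. Default missingness is zero: the profiles
#' emulate complete-case analysis cohorts; raw-extract missingness is opt-in
#' via the `missingness` field or [apply_missingness()].
#'
#' @param n_patients Optional named vector overriding per-site cohort sizes.
#' @return A named list of [site_profile()] objects.
#' @export
default_site_profiles <- function(n_patients = NULL) {
  ref <- cohort_reference_counts()
  shifts <- c(hospital_1a = 0, hospital_2 = 8, hospital_3 = -5, hospital_1b = 3)
  eth_tweaks <- list(
    hospital_1a = c("Indian" = 0.08, "African" = 0.07, "Caribbean" = 0.05,
                    "Any other White background" = 0.12),
    hospital_2  = c("Indian" = 0.02, "African" = 0.01, "Caribbean" = 0.01),
    hospital_3  = c("Pakistani" = 0.06, "Indian" = 0.07),
    hospital_1b = c("Indian" = 0.08, "African" = 0.06, "Caribbean" = 0.04,
                    "Any other White background" = 0.10))
  profiles <- lapply(seq_len(nrow(ref)), function(i) {
    row <- ref[i, ]
    n <- if (!is.null(n_patients) && row$site %in% names(n_patients)) {
      n_patients[[row$site]]
    } else {
      row$n_patients
    }
    mix <- default_ethnicity_mix()
    tweak <- eth_tweaks[[row$site]]
    mix[names(tweak)] <- tweak
    mix["British"] <- 0
    mix["British"] <- 1 - sum(mix)
    tumours <- c(breast = row$breast, bowel = row$bowel, dlbcl = row$dlbcl,
                 lung = row$lung, ovarian = row$ovarian)
    site_profile(
      site_id = row$site, n_patients = n,
      age = c(row$age_median, row$age_min, row$age_max, 13),
      sex_female = row$female / (row$female + row$male),
      ethnicity_mix = mix,
      tumour_mix = tumours / sum(tumours),
      creatinine_shift = shifts[[row$site]],
      toxicity_rates = c(creatinine = row$creatinine_changes / row$n_patients,
                         bilirubin = row$bilirubin_changes / row$n_patients),
      temporal_shift = row$temporal_shift)
  })
  setNames(profiles, ref$site)
}

#' Generator configuration
#'
#' @param sites List of [site_profile()] objects.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @param toxicity_effect List with `cycle_probs` (probability of the injected
#'   event falling at cycles 3--6; must sum to 1) and `multiplier` (> 1.5): from
#'   the event cycle onward the affected analyte is drawn around
#'   `multiplier x max(baseline, ULN)` (creatinine) or `multiplier x ULN`
#'   (bilirubin), a sustained step that clears the grade-1 boundary of the
#'   CTCAE-style ladder so injected events are recoverable by the labeller.
#' @param autocorrelation Within-patient serial correlation of log-lab noise,
#'   in `[0, 1)`.
#' @param lab_noise_sd Standard deviation of the log-scale lab noise.
#' @param regimen_risk Optional list `list(regimen = <name>, rates = c(...))`
#'   tying outcome risk to one specific regimen: patients receiving it have
#'   their per-analyte event probabilities replaced by `rates`. Used for the
#'   subgroup-aggregation information-loss experiments.
#' @return A `generator_config` object.
#' @export
generator_config <- function(sites = default_site_profiles(),
                             seed = 1L,
                             toxicity_effect = list(
                               cycle_probs = c(0.25, 0.25, 0.25, 0.25),
                               multiplier = 2),
                             autocorrelation = 0.6,
                             lab_noise_sd = 0.08,
                             regimen_risk = NULL) {
  if (inherits(sites, "site_profile")) sites <- list(sites)
  if (!length(sites) || !all(vapply(sites, inherits, TRUE, "site_profile"))) {
    config_abort("sites", "must be a list of site_profile objects")
  }
  check_mix(toxicity_effect$cycle_probs, "toxicity_effect$cycle_probs")
  if (length(toxicity_effect$cycle_probs) != 4) {
    config_abort("toxicity_effect$cycle_probs", "must cover cycles 3-6 (length 4)")
  }
  if (toxicity_effect$multiplier <= 1.5) {
    config_abort("toxicity_effect$multiplier",
                 "must exceed 1.5 so injected events clear the grade-1 boundary")
  }
  if (autocorrelation < 0 || autocorrelation >= 1) {
    config_abort("autocorrelation", "must be in [0, 1)")
  }
  if (lab_noise_sd <= 0) config_abort("lab_noise_sd", "must be > 0")
  if (!is.null(regimen_risk)) {
    if (is.null(regimen_risk$regimen) || is.null(regimen_risk$rates)) {
      config_abort("regimen_risk", "must be list(regimen = , rates = )")
    }
    check_prob(regimen_risk$rates, "regimen_risk$rates")
  }
  structure(
    list(sites = sites, seed = as.integer(seed), cycles = 6L,
         toxicity_effect = toxicity_effect, autocorrelation = autocorrelation,
         lab_noise_sd = lab_noise_sd, regimen_risk = regimen_risk),
    class = "generator_config")
}

# Relative log-noise scale per analyte (creatinine varies day-to-day less than
# ANC, which is strongly treatment-driven).
noise_scale <- c(creatinine = 1, bilirubin = 1.2, haemoglobin = 0.5,
                 anc = 1.8, alt = 1.5)

#' Generate a multi-site synthetic cohort
#'
#' Draws demographics, regimens, comorbidities, baseline labs and longitudinal
#' per-cycle blood panels (baseline plus cycles 1--6) for every site in the
#' configuration. Lab trajectories are `baseline x lognormal AR(1)` noise;
#' injected toxicity events add a sustained multiplicative step from the event
#' cycle onward (see [generator_config()]), and are recorded in a hidden
#' ground-truth event table so downstream labelling can be validated. Panel
#' missingness is applied after event injection.
#'
#' @param config A [generator_config()].
#' @return A `chemo_cohort`: list with tibbles `patients`, `observations` and
#'   the ground-truth `events` (`patient_id`, `analyte`, `event_cycle`).
#' @export
#' @examples
#' sites <- list(site_profile("a", 50, toxicity_rates = c(creatinine = 0.15, bilirubin = 0.1)))
#' cohort <- generate_cohort(generator_config(sites, seed = 7))
#' dplyr::count(cohort$patients, tumour_type)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_local_seed(config$seed, {
    pieces <- lapply(config$sites, generate_site, config = config)
    cohort <- structure(
      list(patients = dplyr::bind_rows(lapply(pieces, `[[`, "patients")),
           observations = dplyr::bind_rows(lapply(pieces, `[[`, "observations")),
           events = dplyr::bind_rows(lapply(pieces, `[[`, "events"))),
      class = "chemo_cohort")
    attr(cohort, "config") <- config
    cohort
  })
}

generate_site <- function(profile, config) {
  n <- profile$n_patients
  if (isTRUE(getOption("chemotox.verbose", FALSE))) {
    inform(sprintf("generating site %s: %d patients", profile$site_id, n))
  }
  regs <- regimen_reference()

  id <- sprintf("%s_p%04d", profile$site_id, seq_len(n))
  age <- round(rnorm_trunc(n, profile$age[1], profile$age[4],
                           profile$age[2], profile$age[3]))
  sex <- ifelse(runif(n) < profile$sex_female, "female", "male")
  ethnicity <- sample(names(profile$ethnicity_mix), n, replace = TRUE,
                      prob = profile$ethnicity_mix)
  tumour <- sample(names(profile$tumour_mix), n, replace = TRUE,
                   prob = profile$tumour_mix)
  regimen <- vapply(tumour, function(tt) {
    opts <- regs$regimen[regs$tumour_type == tt]
    opts[sample.int(length(opts), 1)]
  }, character(1), USE.NAMES = FALSE)
  n_drugs <- regs$n_drugs[match(regimen, regs$regimen)]

  height <- ifelse(sex == "female", rnorm(n, 163, 7), rnorm(n, 176, 8))
  weight <- ifelse(sex == "female", rnorm(n, 70, 14), rnorm(n, 83, 15))
  height[runif(n) < 0.05] <- NA
  weight[runif(n) < 0.05] <- NA
  rdi <- round(runif(n, 0.75, 1.05), 3)
  rdi[runif(n) < 0.1] <- NA

  comorb_probs <- c(diabetes = 0.12, cardiovascular = 0.18, thyroid = 0.07,
                    respiratory = 0.10, arthritis = 0.08, autoimmune = 0.04)
  comorbs <- as_tibble(lapply(comorb_probs, function(p) runif(n) < p))
  names(comorbs) <- paste0("comorb_", names(comorb_probs))
  not_collected <- runif(n) < 0.1
  comorbs[not_collected, ] <- NA

  patients <- tibble(
    patient_id = id, site = profile$site_id, age = age, sex = sex,
    ethnicity_fine = ethnicity, height = round(height, 1),
    weight = round(weight, 1), tumour_type = tumour, regimen = regimen,
    n_drugs = n_drugs, relative_dose_intensity = rdi, first_line = TRUE) |>
    dplyr::bind_cols(comorbs)

  # Baseline labs: site creatinine shift, sex offsets for creatinine and
  # haemoglobin, temporal drift on every mean.
  labs0 <- lapply(analytes(), function(a) {
    p <- profile$baseline_labs[[a]]
    mean <- p[1] * profile$temporal_shift
    if (a == "creatinine") {
      mean <- mean + profile$creatinine_shift + ifelse(sex == "male", 10, -5)
    }
    if (a == "haemoglobin") mean <- mean + ifelse(sex == "male", 6, -4)
    rnorm_trunc(n, mean, p[2], lower = pmax(mean / 4, 0.5))
  })
  names(labs0) <- analytes()

  # Injected toxicity events: per-analyte Bernoulli at the site rate (or the
  # regimen-tied override), event cycle drawn over 3-6.
  events <- dplyr::bind_rows(lapply(graded_analytes(), function(a) {
    rate <- rep(profile$toxicity_rates[[a]], n)
    rr <- config$regimen_risk
    if (!is.null(rr) && a %in% names(rr$rates)) {
      rate[regimen == rr$regimen] <- rr$rates[[a]]
    }
    hit <- runif(n) < rate
    k <- sum(hit)
    if (k == 0) return(tibble(patient_id = character(), analyte = character(),
                              event_cycle = integer()))
    tibble(patient_id = id[hit], analyte = a,
           event_cycle = sample(3:6, k, replace = TRUE,
                                prob = config$toxicity_effect$cycle_probs))
  }))

  # Treatment-day offsets: baseline one week before cycle 1 (day 0), then
  # roughly 21-day cycles with jitter.
  gaps <- matrix(pmin(pmax(round(rnorm(n * 5, 21, 2)), 14), 35), nrow = n)
  day_offsets <- cbind(-7L, 0L, t(apply(gaps, 1, cumsum)))

  rho <- config$autocorrelation
  sdl <- config$lab_noise_sd
  mult <- config$toxicity_effect$multiplier
  obs <- lapply(analytes(), function(a) {
    sdl_a <- sdl * noise_scale[[a]]
    e <- matrix(0, n, 7)
    e[, 1] <- rnorm(n, 0, sdl_a)
    for (c in 2:7) e[, c] <- rho * e[, c - 1] + sqrt(1 - rho^2) * rnorm(n, 0, sdl_a)
    vals <- labs0[[a]] * exp(e)
    vals[, 1] <- labs0[[a]] # cycle-0 observation is the drawn baseline itself
    if (a == "haemoglobin") {
      vals <- vals * matrix(rep(1 - 0.015 * (0:6), each = n), n, 7)
      vals[, 1] <- labs0[[a]]
    }
    if (a %in% graded_analytes()) {
      ev <- events[events$analyte == a, ]
      if (nrow(ev)) {
        idx <- match(ev$patient_id, id)
        uln <- default_uln(a, sex[idx])
        ref <- if (a == "creatinine") pmax(labs0[[a]][idx], uln) else uln
        for (j in seq_along(idx)) {
          cyc <- (ev$event_cycle[j] + 1):7
          vals[idx[j], cyc] <- mult * ref[j] * exp(e[idx[j], cyc])
        }
      }
    }
    round(vals, 1)
  })
  names(obs) <- analytes()

  observations <- tibble(
    patient_id = rep(id, each = 7), cycle = rep(0:6, n),
    day_offset = as.integer(t(day_offsets)),
    creatinine = as.vector(t(obs$creatinine)),
    bilirubin = as.vector(t(obs$bilirubin)),
    haemoglobin = as.vector(t(obs$haemoglobin)),
    anc = round(as.vector(t(obs$anc)), 2),
    alt = as.vector(t(obs$alt)))

  if (any(profile$missingness > 0)) {
    observations <- apply_missingness(observations, profile$missingness,
                                      seed = NULL)
  }
  list(patients = patients, observations = observations, events = events)
}

#' Blank blood panels according to a per-cycle missingness curve
#'
#' Emulates blood-test missingness that increases with treatment progression:
#' for each treatment cycle (never the baseline), a patient's whole five-test
#' panel is set missing with the cycle's probability. The curve must be
#' monotone non-decreasing.
#'
#' @param observations An observations tibble (or a `chemo_cohort`, in which
#'   case its observations are blanked and the cohort returned).
#' @param curve Length-7 per-cycle (0--6) missingness probabilities.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return Object of the same shape with lab values blanked.
#' @export
apply_missingness <- function(observations, curve, seed = NULL) {
  check_missingness_curve(curve)
  if (inherits(observations, "chemo_cohort")) {
    observations$observations <-
      apply_missingness(observations$observations, curve, seed)
    return(observations)
  }
  with_local_seed(seed, {
    drop <- runif(nrow(observations)) < curve[observations$cycle + 1] &
      observations$cycle > 0
    observations[drop, analytes()] <- NA_real_
    observations
  })
}

#' @export
print.chemo_cohort <- function(x, ...) {
  cat(sprintf("<chemo_cohort> %d patients, %d sites, %d observation rows, %d injected events\n",
              nrow(x$patients), dplyr::n_distinct(x$patients$site),
              nrow(x$observations), nrow(x$events)))
  invisible(x)
}

#' Write / read a cohort as plain CSV files
#'
#' `write_cohort()` writes `patients.csv` and `observations.csv` (and, when
#' `include_events = TRUE`, the hidden ground-truth `events.csv` intended for
#' testing only) into `dir`; output is byte-stable for a fixed cohort.
#'
#' @param cohort A `chemo_cohort`.
#' @param dir Output directory (created if needed).
#' @param include_events Also write the ground-truth event table.
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` returns a
#'   `chemo_cohort`.
#' @export
write_cohort <- function(cohort, dir, include_events = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(cohort$patients, file.path(dir, "patients.csv"), progress = FALSE)
  readr::write_csv(cohort$observations, file.path(dir, "observations.csv"), progress = FALSE)
  if (include_events && !is.null(cohort$events)) {
    readr::write_csv(cohort$events, file.path(dir, "events.csv"), progress = FALSE)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  ev <- file.path(dir, "events.csv")
  structure(
    list(patients = readr::read_csv(file.path(dir, "patients.csv"),
                                    show_col_types = FALSE, progress = FALSE),
         observations = readr::read_csv(file.path(dir, "observations.csv"),
                                        show_col_types = FALSE, progress = FALSE),
         events = if (file.exists(ev)) readr::read_csv(ev, show_col_types = FALSE,
                                                       progress = FALSE)),
    class = "chemo_cohort")
}
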