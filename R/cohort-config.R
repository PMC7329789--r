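#' Synthetic cohort configuration
#'
#' Builds and validates the configuration for the synthetic fertility-survey
#' generator. The generator simulates a finite superpopulation of women,
#' organised as design strata each containing several primary sampling units
#' (PSUs), and draws a stratified, clustered, weighted sample from it. Every
#' woman carries demographic attributes and a dated pregnancy-event history,
#' so the true annual event counts of the superpopulation are known exactly
#' and all downstream estimators can be validated by parameter recovery.
#'
#' @param n_strata number of design strata.
#' @param psus_per_stratum number of PSUs sampled per stratum.
#' @param women_per_psu number of women sampled per PSU.
#' @param pop_per_psu superpopulation women represented by each PSU; the
#'   inverse inclusion probability is `pop_per_psu / women_per_psu`.
#' @param interview_years named numeric vector mapping calendar interview
#'   year to its sampling proportion (proportions sum to 1).
#' @param age_range integer vector `c(min, max)`: age in years at interview.
#' @param age_bands named proportion vector over age bands at interview;
#'   names use the form `"15-19"`.
#' @param category_mixes named list of demographic axes (race, religion,
#'   poverty, nativity, education, union), each a named proportion vector.
#' @param event_years calendar years over which pregnancy events are
#'   generated for the whole superpopulation. Defaults to the eight years
#'   preceding the earliest interview year through the year before the
#'   latest one.
#' @param annual_event_rates list keyed by outcome
#'   (`birth`, `stillbirth`, `miscarriage`, `abortion`); each element is a
#'   list with `base` (events per woman-year, in \[0, 1\]) and optional
#'   `multipliers`, a named list `axis -> named multiplier vector` applied
#'   multiplicatively to the base rate.
#' @param gestation_mix named proportion vector over gestation bands
#'   (`"<9"`, `"9-12"`, `"13+"` weeks), used for abortion events only.
#' @param union_stability probability that union status at the event equals
#'   union status at interview; otherwise redrawn from the union mix.
#' @param psu_sigma standard deviation of a log-scale PSU-level random
#'   intercept on event rates (induces within-PSU correlation; default 0).
#' @param weight_dispersion `sdlog` of multiplicative lognormal noise on the
#'   base weights before ratio calibration to the superpopulation total.
#' @param min_event_age youngest age at which events are generated.
#' @param reporting_model named list per survey mode; each mode is a list
#'   with `intercept` (log-odds) and optional `terms`, a named list mapping
#'   an event- or woman-level attribute (e.g. `outcome`, `race`,
#'   `age_band_at_event`, `gestation_band`, `parity_cat`, `union_at_event`)
#'   to a named vector of log-odds offsets per category.
#' @param seed default random seed for this configuration.
#'
#' @return an object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()], [apply_reporting_model()]
#' @export
#' @examples
#' cfg <- cohort_config(n_strata = 2, psus_per_stratum = 3,
#'                      women_per_psu = 10, pop_per_psu = 50)
#' cfg$annual_event_rates$abortion$base
cohort_config <- function(n_strata = 4,
                          psus_per_stratum = 6,
                          women_per_psu = 25,
                          pop_per_psu = 250,
                          interview_years = c("2012" = 0.5, "2013" = 0.5),
                          age_range = c(15L, 44L),
                          age_bands = c("15-19" = 0.17, "20-29" = 0.34,
                                        "30-44" = 0.49),
                          category_mixes = default_category_mixes(),
                          event_years = NULL,
                          annual_event_rates = default_event_rates(),
                          gestation_mix = c("<9" = 0.65, "9-12" = 0.25,
                                            "13+" = 0.10),
                          union_stability = 0.8,
                          psu_sigma = 0,
                          weight_dispersion = 0,
                          min_event_age = NULL,
                          reporting_model = default_reporting_model(),
                          seed = 1L) {
  if (is.null(event_years)) {
    iy <- as.integer(names(interview_years))
    event_years <- seq.int(min(iy) - 8L, max(iy) - 1L)
  }
  cfg <- structure(list(
    n_strata = as.integer(n_strata),
    psus_per_stratum = as.integer(psus_per_stratum),
    women_per_psu = as.integer(women_per_psu),
    pop_per_psu = as.integer(pop_per_psu),
    interview_years = interview_years,
    age_range = as.integer(age_range),
    age_bands = age_bands,
    category_mixes = category_mixes,
    event_years = as.integer(event_years),
    annual_event_rates = annual_event_rates,
    gestation_mix = gestation_mix,
    union_stability = union_stability,
    psu_sigma = psu_sigma,
    weight_dispersion = weight_dispersion,
    min_event_age = as.integer(min_event_age %||% age_range[1]),
    reporting_model = reporting_model,
    seed = as.integer(seed)
  ), class = "cohort_config")
  errs <- validate_cohort_config(cfg)
  if (length(errs)) {
    stop("invalid cohort configuration:\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  }
  cfg
}

#' Default demographic category mixes
#'
#' Marginal distributions loosely patterned on the composition of recent
#' U.S. fertility-survey samples of women aged 15-44.
#'
#' @return named list of named proportion vectors.
#' @export
default_category_mixes <- function() {
  list(
    race = c(white = 0.58, black = 0.15, hispanic = 0.20, other = 0.07),
    religion = c(protestant = 0.47, catholic = 0.22, other = 0.09,
                 none = 0.22),
    poverty = c("lt100" = 0.28, "100to199" = 0.21, "200plus" = 0.51),
    nativity = c(us_born = 0.84, foreign_born = 0.16),
    education = c(lt_hs = 0.18, hs = 0.24, some_college = 0.30,
                  college = 0.28),
    union = c(married = 0.38, cohabiting = 0.15, formerly_married = 0.08,
              never_married = 0.39)
  )
}

#' Default annual pregnancy-outcome rates
#'
#' Events per woman-year, roughly matching recent U.S. levels for women
#' aged 15-44 (births about 60 per 1,000, abortions about 17 per 1,000).
#'
#' @return list keyed by outcome with `base` rates.
#' @export
default_event_rates <- function() {
  list(
    birth = list(base = 0.060),
    stillbirth = list(base = 0.0004),
    miscarriage = list(base = 0.012),
    abortion = list(base = 0.017)
  )
}

#' Default two-mode reporting model
#'
#' A face-to-face (`ftf`) mode and a self-administered (`acasi`) mode.
#' Births are reported nearly completely in both; abortion reporting is
#' substantially less complete face-to-face than in the private mode,
#' the contrast repeatedly documented for sensitive pregnancy outcomes.
#'
#' @return named list of per-mode reporting models (log-odds scale).
#' @export
default_reporting_model <- function() {
  list(
    ftf = list(intercept = 0, terms = list(
      outcome = c(birth = logit(0.98), stillbirth = logit(0.90),
                  miscarriage = logit(0.70), abortion = logit(0.40))
    )),
    acasi = list(intercept = 0, terms = list(
      outcome = c(birth = logit(0.98), stillbirth = logit(0.90),
                  miscarriage = logit(0.80), abortion = logit(0.72))
    ))
  )
}

#' Validate a cohort configuration
#'
#' Checks all cross-field invariants and returns every violation found
#' (not just the first), each naming the offending field.
#'
#' @param cfg a `cohort_config` or a plain list with the same fields.
#' @return character vector of error messages; empty if valid.
#' @export
validate_cohort_config <- function(cfg) {
  errs <- character(0)
  for (f in c("n_strata", "psus_per_stratum", "women_per_psu",
              "pop_per_psu")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1) {
      errs <- c(errs, sprintf("%s: must be a positive integer", f))
    }
  }
  if (is.numeric(cfg$women_per_psu) && is.numeric(cfg$pop_per_psu) &&
      length(cfg$women_per_psu) == 1L && length(cfg$pop_per_psu) == 1L &&
      !is.na(cfg$women_per_psu) && !is.na(cfg$pop_per_psu) &&
      cfg$women_per_psu > cfg$pop_per_psu) {
    errs <- c(errs, "women_per_psu: exceeds pop_per_psu")
  }
  if (length(cfg$interview_years) == 0L) {
    errs <- c(errs, "interview_years: must be nonempty")
  } else {
    errs <- c(errs, check_proportions(cfg$interview_years, "interview_years"))
  }
  if (length(cfg$age_range) != 2L || cfg$age_range[1] > cfg$age_range[2]) {
    errs <- c(errs, "age_range: must be c(min, max) with min <= max")
  }
  errs <- c(errs, check_proportions(cfg$age_bands, "age_bands"))
  bands <- tryCatch(parse_age_bands(names(cfg$age_bands)),
                    error = function(e) NULL)
  if (is.null(bands)) {
    errs <- c(errs, "age_bands: names must look like \"15-19\"")
  }
  for (axis in names(cfg$category_mixes)) {
    errs <- c(errs, check_proportions(cfg$category_mixes[[axis]],
                                      sprintf("category_mixes$%s", axis)))
  }
  for (oc in names(cfg$annual_event_rates)) {
    r <- cfg$annual_event_rates[[oc]]$base
    if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0 || r > 1) {
      errs <- c(errs,
                sprintf("annual_event_rates$%s$base: must be in [0, 1]", oc))
    }
    mult <- cfg$annual_event_rates[[oc]]$multipliers
    for (axis in names(mult)) {
      if (any(mult[[axis]] < 0)) {
        errs <- c(errs, sprintf(
          "annual_event_rates$%s$multipliers$%s: negative multiplier",
          oc, axis))
      }
    }
  }
  errs <- c(errs, check_proportions(cfg$gestation_mix, "gestation_mix"))
  if (!is.numeric(cfg$union_stability) || cfg$union_stability < 0 ||
      cfg$union_stability > 1) {
    errs <- c(errs, "union_stability: must be in [0, 1]")
  }
  if (!is.numeric(cfg$psu_sigma) || cfg$psu_sigma < 0) {
    errs <- c(errs, "psu_sigma: must be nonnegative")
  }
  if (!is.numeric(cfg$weight_dispersion) || cfg$weight_dispersion < 0) {
    errs <- c(errs, "weight_dispersion: must be nonnegative")
  }
  for (mode in names(cfg$reporting_model)) {
    m <- cfg$reporting_model[[mode]]
    if (!is.numeric(m$intercept %||% NA_real_)) {
      errs <- c(errs, sprintf("reporting_model$%s$intercept: missing", mode))
    }
  }
  errs
}

# Parse band labels like "15-19" into a data.frame(lo, hi).
parse_age_bands <- function(labels) {
  m <- regmatches(labels, regexec("^([0-9]+)-([0-9]+)$", labels))
  if (any(vapply(m, length, 1L) != 3L)) {
    stop("age band labels must look like \"15-19\"")
  }
  lo <- vapply(m, function(x) as.integer(x[2]), 1L)
  hi <- vapply(m, function(x) as.integer(x[3]), 1L)
  if (any(lo > hi)) stop("age band lower bound exceeds upper bound")
  data.frame(label = labels, lo = lo, hi = hi, stringsAsFactors = FALSE)
}

# Label ages with configured bands, extending below/above with open bands
# so truth tabulations never drop an event.
age_to_band <- function(age, age_bands) {
  bands <- parse_age_bands(names(age_bands))
  lab <- rep(NA_character_, length(age))
  for (i in seq_len(nrow(bands))) {
    sel <- age >= bands$lo[i] & age <= bands$hi[i]
    lab[sel] <- bands$label[i]
  }
  lab[!is.na(age) & age < min(bands$lo)] <- sprintf("<%d", min(bands$lo))
  lab[!is.na(age) & age > max(bands$hi)] <- sprintf("%d+", max(bands$hi) + 1L)
  lab
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  design: %d strata x %d PSUs x %d women sampled (of %d) per PSU\n",
              x$n_strata, x$psus_per_stratum, x$women_per_psu, x$pop_per_psu))
  cat(sprintf("  interview years: %s\n",
              paste(names(x$interview_years), collapse = ", ")))
  cat(sprintf("  event years: %d-%d\n", min(x$event_years),
              max(x$event_years)))
  cat(sprintf("  outcomes: %s\n",
              paste(names(x$annual_event_rates), collapse = ", ")))
  cat(sprintf("  modes: %s\n", paste(names(x$reporting_model),
                                     collapse = ", ")))
  invisible(x)
}
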