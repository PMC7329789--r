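# Shared fixtures, all built in code.

# Small design used where the content of the cohort matters more than its
# size: 2 strata x 3 PSUs, single interview year.
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_strata = 2, psus_per_stratum = 3, women_per_psu = 15,
         pop_per_psu = 60,
         interview_years = c("2012" = 1),
         event_years = 2006:2011),
    list(...))
  do.call(cohort_config, args)
}

# Intercept-only reporting model: one mode, constant probability s for
# every event regardless of outcome or attributes.
constant_reporting <- function(s, mode = "ftf") {
  stats::setNames(list(list(intercept = stats::qlogis(s), terms = list())),
                  mode)
}

# Hand-built cohort for exact-arithmetic estimator checks: weights and
# events are fully specified, design is 2 strata x 2 PSUs.
manual_cohort <- function(weights, event_woman, event_year,
                          interview_year = 2012, outcome = "abortion") {
  n <- length(weights)
  women <- data.frame(
    woman_id = seq_len(n),
    stratum_id = rep(1:2, length.out = n),
    psu_id = rep(1:4, length.out = n),
    base_weight = weights,
    interview_year = interview_year,
    interview_month = 6L,
    age = 30L, age_band = "30-44",
    race = "white", religion = "none", poverty = "200plus",
    nativity = "us_born", education = "college", union = "married",
    stringsAsFactors = FALSE)
  events <- data.frame(
    woman_id = event_woman,
    outcome = outcome,
    end_year = event_year,
    end_month = 6L,
    age_at_event = 25L,
    gestation_band = ifelse(outcome == "abortion", "<9", NA_character_),
    union_at_event = "married",
    parity_before_event = 0L,
    stringsAsFactors = FALSE)
  structure(list(women = women, events = events, truth = NULL,
                 config = cohort_config(), seed = 1L),
            class = "synthetic_cohort")
}

# Toy external table: totals only, one outcome.
toy_totals_table <- function(years, counts, outcome = "abortion") {
  external_counts(data.frame(year = years, outcome = outcome,
                             axis = "total", category = "all",
                             count = counts))
}
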