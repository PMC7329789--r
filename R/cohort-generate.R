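#' Generate a synthetic survey cohort with known truth
#'
#' Simulates the full finite superpopulation described by the
#' configuration — every woman in every PSU of every stratum, with
#' demographic attributes and a dated pregnancy-event history at month
#' resolution — then draws the stratified, clustered sample and attaches
#' design weights. Because the whole superpopulation is realised, the true
#' annual event counts by subgroup are tabulated exactly into an
#' [external_counts] table.
#'
#' Two details matter for downstream validation:
#' \itemize{
#' \item The superpopulation keeps generating events after a woman's
#'   interview date; only events that precede her interview month enter her
#'   survey record. True calendar-year counts are therefore independent of
#'   the interview-year mix, matching how real benchmark counts are
#'   compiled.
#' \item Base weights are inverse inclusion probabilities times optional
#'   lognormal noise, then ratio-calibrated so they sum to the
#'   superpopulation size (emulating poststratification). With
#'   `weight_dispersion = 0` the calibration is exact by construction.
#' }
#'
#' @param config a [cohort_config].
#' @param seed integer seed; defaults to `config$seed`. The same config and
#'   seed always reproduce byte-identical output.
#' @return an object of class `synthetic_cohort`: a list with
#'   \describe{
#'     \item{women}{data.frame, one row per sampled woman (design position,
#'       weight, interview date, demographic attributes).}
#'     \item{events}{data.frame, one row per pregnancy event of a sampled
#'       woman that ended before her interview (foreign key `woman_id`).}
#'     \item{truth}{[external_counts] table of exact superpopulation event
#'       counts by year, outcome and subgroup.}
#'     \item{config, seed}{the inputs.}
#'   }
#' @export
#' @examples
#' cfg <- cohort_config(n_strata = 2, psus_per_stratum = 2,
#'                      women_per_psu = 5, pop_per_psu = 20)
#' coh <- generate_cohort(cfg, seed = 7)
#' nrow(coh$women)  # 2 * 2 * 5
generate_cohort <- function(config, seed = config$seed) {
  errs <- validate_cohort_config(config)
  if (length(errs)) {
    stop("invalid cohort configuration:\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  }
  set.seed(mix_seed(seed, 1L))
  H <- config$n_strata
  K <- config$psus_per_stratum
  n_psu <- H * K
  N <- n_psu * config$pop_per_psu

  stratum_id <- rep(seq_len(H), each = K * config$pop_per_psu)
  psu_id <- rep(seq_len(n_psu), each = config$pop_per_psu)
  woman_id <- seq_len(N)

  # interview date and attributes at interview
  iy <- as.integer(sample(names(config$interview_years), N, replace = TRUE,
                          prob = config$interview_years))
  im <- sample.int(12L, N, replace = TRUE)
  band <- sample(names(config$age_bands), N, replace = TRUE,
                 prob = config$age_bands)
  bdef <- parse_age_bands(names(config$age_bands))
  lo <- pmax(bdef$lo[match(band, bdef$label)], config$age_range[1])
  hi <- pmin(bdef$hi[match(band, bdef$label)], config$age_range[2])
  age <- lo + floor(stats::runif(N) * (hi - lo + 1L))

  attrs <- lapply(config$category_mixes, function(mix) {
    sample(names(mix), N, replace = TRUE, prob = mix)
  })

  pop <- data.frame(woman_id, stratum_id, psu_id,
                    interview_year = iy, interview_month = im,
                    age = age, age_band = band,
                    stringsAsFactors = FALSE)
  for (ax in names(attrs)) pop[[ax]] <- attrs[[ax]]

  events <- generate_events(pop, config)

  truth <- tabulate_truth(events, pop, config)

  # stratified cluster sample: women_per_psu per PSU, equal probability
  sel <- unlist(lapply(seq_len(n_psu), function(p) {
    ids <- woman_id[psu_id == p]
    sample(ids, config$women_per_psu)
  }), use.names = FALSE)
  women <- pop[match(sort(sel), pop$woman_id), , drop = FALSE]
  rownames(women) <- NULL
  base_w <- rep(config$pop_per_psu / config$women_per_psu, nrow(women))
  if (config$weight_dispersion > 0) {
    base_w <- base_w * stats::rlnorm(nrow(women), meanlog = 0,
                                     sdlog = config$weight_dispersion)
  }
  women$base_weight <- base_w * N / sum(base_w)  # ratio calibration

  # survey record: only events ending before the interview month
  ev <- events[events$woman_id %in% women$woman_id, , drop = FALSE]
  t_ev <- ev$end_year * 12L + ev$end_month
  wi <- match(ev$woman_id, women$woman_id)
  t_int <- women$interview_year[wi] * 12L + women$interview_month[wi]
  ev <- ev[t_ev < t_int, , drop = FALSE]
  rownames(ev) <- NULL

  structure(list(women = women, events = ev, truth = truth,
                 config = config, seed = as.integer(seed)),
            class = "synthetic_cohort")
}

# Event histories for the full superpopulation. One Bernoulli trial per
# woman-year-outcome at the configured annual rate (rates are in [0,1]),
# optionally modulated by subgroup multipliers and a PSU-level random
# intercept on the rate scale.
generate_events <- function(pop, config) {
  N <- nrow(pop)
  yrs <- config$event_years
  idx <- rep(seq_len(N), times = length(yrs))
  yr <- rep(yrs, each = N)
  age_ev <- pop$age[idx] - (pop$interview_year[idx] - yr)
  keep <- age_ev >= config$min_event_age
  idx <- idx[keep]; yr <- yr[keep]; age_ev <- age_ev[keep]
  n_grid <- length(idx)

  psu_u <- if (config$psu_sigma > 0) {
    stats::rnorm(max(pop$psu_id), 0, config$psu_sigma)
  } else {
    rep(0, max(pop$psu_id))
  }
  psu_mult <- exp(psu_u[pop$psu_id[idx]])

  out <- vector("list", length(config$annual_event_rates))
  names(out) <- names(config$annual_event_rates)
  for (oc in names(config$annual_event_rates)) {
    spec <- config$annual_event_rates[[oc]]
    rate <- rep(spec$base, n_grid)
    for (ax in names(spec$multipliers)) {
      mv <- spec$multipliers[[ax]]
      if (!ax %in% names(pop)) {
        stop(sprintf(
          "annual_event_rates$%s$multipliers: unknown axis '%s'", oc, ax))
      }
      m <- mv[pop[[ax]][idx]]
      m[is.na(m)] <- 1
      rate <- rate * m
    }
    rate <- pmin(1, rate * psu_mult)
    hit <- stats::runif(n_grid) < rate
    if (!any(hit)) next
    out[[oc]] <- data.frame(
      woman_id = pop$woman_id[idx[hit]],
      outcome = oc,
      end_year = yr[hit],
      end_month = sample.int(12L, sum(hit), replace = TRUE),
      age_at_event = age_ev[hit],
      stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(ev) || nrow(ev) == 0L) {
    return(data.frame(woman_id = integer(0), outcome = character(0),
                      end_year = integer(0), end_month = integer(0),
                      age_at_event = integer(0),
                      gestation_band = character(0),
                      union_at_event = character(0),
                      parity_before_event = integer(0),
                      stringsAsFactors = FALSE))
  }
  ev <- ev[order(ev$woman_id, ev$end_year, ev$end_month), , drop = FALSE]
  rownames(ev) <- NULL

  # gestation band recorded for abortions only
  ev$gestation_band <- NA_character_
  ab <- ev$outcome == "abortion"
  if (any(ab)) {
    ev$gestation_band[ab] <- sample(names(config$gestation_mix), sum(ab),
                                    replace = TRUE,
                                    prob = config$gestation_mix)
  }

  # union at event: sticky to interview status, else redrawn from the mix
  wu <- pop$union[match(ev$woman_id, pop$woman_id)]
  sticky <- stats::runif(nrow(ev)) < config$union_stability
  redraw <- sample(names(config$category_mixes$union), nrow(ev),
                   replace = TRUE, prob = config$category_mixes$union)
  ev$union_at_event <- ifelse(sticky, wu, redraw)

  # parity before event: births of the same woman strictly earlier
  t_ev <- ev$end_year * 12L + ev$end_month
  parity <- integer(nrow(ev))
  for (rows in split(seq_len(nrow(ev)), ev$woman_id)) {
    bt <- t_ev[rows][ev$outcome[rows] == "birth"]
    parity[rows] <- vapply(t_ev[rows], function(t) sum(bt < t), 0L)
  }
  ev$parity_before_event <- parity
  ev
}

# Exact superpopulation counts by year, outcome and subgroup.
tabulate_truth <- function(events, pop, config) {
  if (nrow(events) == 0L) {
    grid <- expand.grid(year = config$event_years,
                        outcome = names(config$annual_event_rates),
                        stringsAsFactors = FALSE)
    df <- data.frame(year = grid$year, outcome = grid$outcome,
                     axis = "total", category = "all", count = 0)
    return(external_counts(df))
  }
  wi <- match(events$woman_id, pop$woman_id)
  frame <- data.frame(
    year = events$end_year,
    outcome = events$outcome,
    age_band = age_to_band(events$age_at_event, config$age_bands),
    union = events$union_at_event,
    parity = ifelse(events$parity_before_event == 0L, "0", "1plus"),
    stringsAsFactors = FALSE)
  for (ax in names(config$category_mixes)) {
    if (ax == "union") next  # union axis is measured at the event
    frame[[ax]] <- pop[[ax]][wi]
  }
  frame$gestation_band <- events$gestation_band

  count_by <- function(cat, axis, sel = !is.na(cat)) {
    agg <- stats::aggregate(
      list(count = rep(1, sum(sel))),
      by = list(year = frame$year[sel], outcome = frame$outcome[sel],
                category = cat[sel]),
      FUN = sum)
    agg$axis <- axis
    agg[c("year", "outcome", "axis", "category", "count")]
  }

  tot <- count_by(rep("all", nrow(frame)), "total")
  axes <- setdiff(names(frame), c("year", "outcome", "gestation_band"))
  parts <- lapply(axes, function(ax) count_by(frame[[ax]], ax))
  gest <- if (any(!is.na(frame$gestation_band))) {
    list(count_by(frame$gestation_band, "gestation_band"))
  } else {
    list()
  }
  df <- do.call(rbind, c(list(tot), parts, gest))
  df <- zero_fill_truth(df, frame, config)
  df <- df[order(df$year, df$outcome, df$axis, df$category), ]
  rownames(df) <- NULL
  external_counts(df)
}

# Complete the tabulation with explicit zero rows: every configured
# (year, outcome) gets a total row and a row for every category of every
# axis, so sparse subgroup-year cells read as zero counts rather than
# missing entries.
zero_fill_truth <- function(df, frame, config) {
  years <- config$event_years
  outcomes <- names(config$annual_event_rates)
  axis_cats <- lapply(config$category_mixes, names)
  axis_cats$union <- names(config$category_mixes$union)
  axis_cats$age_band <- union(names(config$age_bands),
                              unique(frame$age_band))
  axis_cats$parity <- c("0", "1plus")
  axis_cats$total <- "all"
  if ("abortion" %in% outcomes) {
    axis_cats$gestation_band <- names(config$gestation_mix)
  }
  filled <- lapply(names(axis_cats), function(ax) {
    ocs <- if (ax == "gestation_band") "abortion" else outcomes
    expand.grid(year = years, outcome = ocs, axis = ax,
                category = axis_cats[[ax]], count = 0,
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  })
  full <- do.call(rbind, filled)
  key <- function(d) paste(d$year, d$outcome, d$axis, d$category)
  miss <- full[!key(full) %in% key(df), , drop = FALSE]
  rbind(df, miss)
}

#' Assign mode-specific reported flags to true events
#'
#' For every survey mode in the configuration's reporting model, each true
#' event receives an independent Bernoulli reported flag with success
#' probability `invlogit(intercept + sum of term offsets)` evaluated on the
#' event's attributes. Flags are only ever attached to events that truly
#' occurred — reporting has perfect specificity by construction; no event
#' is fabricated.
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()] whose events
#'   do not yet carry flags for the modes being assigned.
#' @param seed integer seed (defaults to the cohort's seed); each mode uses
#'   an independent deterministic substream.
#' @param modes character vector of modes to assign; default all modes in
#'   the configuration.
#' @return the cohort with one logical `reported_<mode>` column per mode
#'   added to `events`.
#' @export
apply_reporting_model <- function(cohort, seed = cohort$seed,
                                  modes = names(cohort$config$reporting_model)) {
  config <- cohort$config
  ev <- cohort$events
  af <- reporting_attribute_frame(ev, cohort$women, config)
  for (mode in modes) {
    col <- paste0("reported_", mode)
    if (col %in% names(ev)) {
      stop(sprintf("events already carry reported flags for mode '%s'",
                   mode))
    }
    model <- config$reporting_model[[mode]]
    if (is.null(model)) stop(sprintf("unknown survey mode '%s'", mode))
    lp <- reporting_linear_predictor(model, af, mode)
    set.seed(mix_seed(seed, 7L, match(mode, names(config$reporting_model))))
    ev[[col]] <- stats::runif(nrow(ev)) < invlogit(lp)
  }
  cohort$events <- ev
  cohort
}

# Event-level attribute frame on which reporting-model terms are evaluated.
reporting_attribute_frame <- function(events, women, config) {
  wi <- match(events$woman_id, women$woman_id)
  af <- data.frame(
    outcome = events$outcome,
    gestation_band = events$gestation_band,
    age_band_at_event = age_to_band(events$age_at_event, config$age_bands),
    union_at_event = events$union_at_event,
    parity_cat = ifelse(events$parity_before_event == 0L, "0", "1plus"),
    age_band = women$age_band[wi],
    stringsAsFactors = FALSE)
  for (ax in names(config$category_mixes)) {
    af[[ax]] <- women[[ax]][wi]
  }
  af
}

reporting_linear_predictor <- function(model, af, mode) {
  lp <- rep(model$intercept, nrow(af))
  for (attr in names(model$terms)) {
    if (!attr %in% names(af)) {
      stop(sprintf(
        "reporting_model$%s: unknown attribute '%s' (available: %s)",
        mode, attr, paste(names(af), collapse = ", ")))
    }
    delta <- model$terms[[attr]][af[[attr]]]
    delta[is.na(delta)] <- 0
    lp <- lp + delta
  }
  lp
}

#' Write a synthetic cohort as delimited text
#'
#' Emits `women.csv` (one row per sampled woman), `events.csv` (one row per
#' event, foreign-keyed by `woman_id`) and `external_counts.csv` (the long
#' truth table).
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("women.csv", "events.csv",
                            "external_counts.csv"))
  utils::write.csv(cohort$women, paths[1], row.names = FALSE)
  utils::write.csv(cohort$events, paths[2], row.names = FALSE)
  write_external_counts(cohort$truth, paths[3])
  invisible(paths)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>\n")
  cat(sprintf("  %d women sampled (%d strata x %d PSUs), %d events on record\n",
              nrow(x$women), x$config$n_strata,
              x$config$n_strata * x$config$psus_per_stratum, nrow(x$events)))
  cat(sprintf("  truth table: %d rows over years %d-%d\n",
              nrow(x$truth), min(x$truth$year), max(x$truth$year)))
  invisible(x)
}
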