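#' Design-based weighted event count
#'
#' Estimates the weighted number of events of one outcome falling inside
#' each respondent's recall window (optionally restricted to events
#' reported in a given survey mode and to a subgroup), with a standard
#' error from stratified with-replacement (between-PSU) linearization:
#' woman-level weighted totals are aggregated to PSU totals \eqn{T_{hj}}
#' and \deqn{\widehat{V} = \sum_h \frac{n_h}{n_h - 1}
#'   \sum_j (T_{hj} - \bar T_h)^2,}
#' the standard design-based variance for a total under with-replacement
#' sampling of PSUs within strata. All sampled women contribute to the
#' design (zero-event women anchor their PSU totals at zero). The design
#' degrees of freedom are (number of PSUs) minus (number of strata).
#'
#' A stratum containing a single PSU is an error naming the stratum:
#' silently collapsing or centering lone-PSU strata would change variances
#' invisibly.
#'
#' @param cohort a `synthetic_cohort` (or any list with `women`, `events`
#'   and `config` shaped like one).
#' @param window a `window_spec` from [build_window()]; every interview
#'   year present among the women must have a window.
#' @param outcome outcome label (e.g. `"abortion"`).
#' @param mode optional survey mode: count only events whose
#'   `reported_<mode>` flag is TRUE. `NULL` counts all true events.
#' @param subgroup optional named list `attribute -> allowed categories`
#'   evaluated on event-level attributes (`outcome`, `gestation_band`,
#'   `age_band_at_event`, `union_at_event`, `parity_cat`, the woman's
#'   demographic axes, and her interview `age_band`).
#' @param eligibility optional [eligibility_spec()]: events outside the
#'   eligible age-at-event range or in an excluded category are not
#'   counted, mirroring analyses that restrict the survey and the external
#'   counts to the same frame.
#' @return an object of class `weighted_total`: list with `estimate`,
#'   `standard_error`, `design_df`, `unweighted_n`.
#' @export
weighted_event_count <- function(cohort, window, outcome, mode = NULL,
                                 subgroup = NULL, eligibility = NULL) {
  women <- cohort$women
  events <- cohort$events
  stopifnot(inherits(window, "window_spec"))

  # design check first: lone PSUs are an error regardless of the filter
  psu_by_stratum <- tapply(women$psu_id, women$stratum_id,
                           function(p) length(unique(p)))
  lone <- names(psu_by_stratum)[psu_by_stratum < 2L]
  if (length(lone)) {
    stop(sprintf(
      "stratum %s contains a single PSU; design-based variance undefined",
      paste(lone, collapse = ", ")))
  }

  contrib <- event_window_contribution(cohort, window, outcome, mode,
                                       subgroup, eligibility)
  per_woman <- rep(0, nrow(women))
  if (length(contrib$idx)) {
    agg <- tapply(contrib$coverage, contrib$idx, sum)
    per_woman[as.integer(names(agg))] <- agg
  }
  t_i <- women$base_weight * per_woman
  estimate <- sum(t_i)

  psu_tot <- tapply(t_i, list(women$stratum_id, women$psu_id), sum)
  variance <- 0
  for (h in rownames(psu_tot)) {
    Th <- psu_tot[h, ]
    Th <- Th[!is.na(Th)]
    nh <- length(Th)
    variance <- variance + nh / (nh - 1) * sum((Th - mean(Th))^2)
  }
  structure(list(
    estimate = estimate,
    standard_error = sqrt(variance),
    design_df = as.integer(sum(psu_by_stratum) - length(psu_by_stratum)),
    unweighted_n = as.integer(sum(contrib$coverage > 0))
  ), class = "weighted_total")
}

# Indices (into women) and coverage fractions of qualifying events.
event_window_contribution <- function(cohort, window, outcome, mode,
                                      subgroup, eligibility = NULL) {
  women <- cohort$women
  events <- cohort$events
  keep <- events$outcome == outcome
  if (!is.null(eligibility)) {
    if (!is.null(eligibility$age_range) && !is.list(eligibility$age_range)) {
      keep <- keep & events$age_at_event >= eligibility$age_range[1] &
        events$age_at_event <= eligibility$age_range[2]
    }
    if (length(eligibility$exclude)) {
      af_elig <- reporting_attribute_frame(events, women, cohort$config)
      for (ax in names(eligibility$exclude)) {
        attr <- axis_to_attribute(ax)
        if (!attr %in% names(af_elig)) {
          stop(sprintf("eligibility exclusion: unknown axis '%s'", ax))
        }
        keep <- keep & !af_elig[[attr]] %in% eligibility$exclude[[ax]]
      }
    }
  }
  if (!is.null(mode)) {
    col <- paste0("reported_", mode)
    if (!col %in% names(events)) {
      stop(sprintf(
        "events carry no reported flags for mode '%s'; run apply_reporting_model()",
        mode))
    }
    keep <- keep & events[[col]]
  }
  if (!is.null(subgroup)) {
    af <- reporting_attribute_frame(events, women, cohort$config)
    for (attr in names(subgroup)) {
      if (!attr %in% names(af)) {
        stop(sprintf("subgroup filter: unknown attribute '%s'", attr))
      }
      keep <- keep & af[[attr]] %in% subgroup[[attr]]
    }
  }
  keep[is.na(keep)] <- FALSE
  ev <- events[keep, , drop = FALSE]
  wi <- match(ev$woman_id, women$woman_id)
  iy <- as.character(women$interview_year[wi])
  miss <- setdiff(unique(iy), names(window$windows))
  if (length(miss)) {
    stop(sprintf("no recall window configured for interview year(s) %s",
                 paste(miss, collapse = ", ")))
  }
  coverage <- numeric(nrow(ev))
  for (y in unique(iy)) {
    w <- window$windows[[y]]
    sel <- iy == y
    m <- match(ev$end_year[sel], w$year)
    cv <- w$coverage[m]
    cv[is.na(cv)] <- 0
    coverage[sel] <- cv
  }
  list(idx = wi[coverage > 0], coverage = coverage[coverage > 0])
}

#' Percent of the external count reported in the survey
#'
#' The completeness statistic: `100 * weighted survey count / external
#' count`, with a normal-approximation 95% confidence interval
#' `100 * (estimate +/- 1.96 * SE) / external`. The external benchmark is
#' treated as a fixed gold-standard constant — only survey sampling error
#' enters the interval — and intervals are deliberately not truncated at 0
#' or 100. Display rounding is to the nearest integer, half away from
#' zero.
#'
#' @param numerator a [weighted_total()][weighted_event_count] (or a list
#'   with `estimate` and `standard_error`).
#' @param external positive scalar external benchmark count.
#' @return an object of class `completeness_estimate`: list with
#'   `percent`, `ci_low`, `ci_high`, `numerator`, `denominator`.
#' @export
#' @examples
#' num <- structure(list(estimate = 4575254, standard_error = 0,
#'                       design_df = 100L, unweighted_n = 1180L),
#'                  class = "weighted_total")
#' percent_reported(num, 11413954)$percent  # 40.09 -> displays as 40
percent_reported <- function(numerator, external) {
  if (!is.numeric(external) || length(external) != 1L || external <= 0) {
    stop("external count must be a positive scalar")
  }
  est <- numerator$estimate
  se <- numerator$standard_error
  structure(list(
    percent = 100 * est / external,
    ci_low = 100 * (est - 1.96 * se) / external,
    ci_high = 100 * (est + 1.96 * se) / external,
    numerator = numerator,
    denominator = external
  ), class = "completeness_estimate")
}

#' Non-overlap significance rule for two completeness estimates
#'
#' TRUE iff the two 95% confidence intervals are disjoint; touching
#' endpoints count as overlap. This is a conservative screen: it rejects
#' less often than a formal two-sample test.
#'
#' @param a,b `completeness_estimate` objects (or lists with `ci_low`,
#'   `ci_high`).
#' @return logical.
#' @export
compare_nonoverlap <- function(a, b) {
  stopifnot(is.finite(a$ci_low), is.finite(a$ci_high),
            is.finite(b$ci_low), is.finite(b$ci_high))
  a$ci_high < b$ci_low || b$ci_high < a$ci_low
}

#' External benchmark count over a recall window
#'
#' Pools one category's external counts over the window years:
#' `sum over cohorts of mix * sum over years coverage * count(year)`,
#' optionally scaled by the year's eligibility fraction.
#'
#' @inheritParams adjust_external
#' @param axis,category row selector in the table (defaults: the year
#'   totals).
#' @return scalar windowed external count.
#' @export
external_window_count <- function(table, window, outcome,
                                  axis = "total", category = "all",
                                  eligibility = NULL) {
  out <- 0
  for (iy in names(window$windows)) {
    w <- window$windows[[iy]]
    for (i in seq_len(nrow(w))) {
      y <- w$year[i]
      sel <- table$year == y & table$outcome == outcome &
        table$axis == axis & table$category == category
      if (!any(sel)) {
        stop(sprintf(
          "no external count for year %d, outcome '%s', axis '%s', category '%s'",
          y, outcome, axis, category))
      }
      ef <- eligible_fraction(table, y, outcome, eligibility)
      out <- out + window$mix[[iy]] * w$coverage[i] * sum(table$count[sel]) * ef
    }
  }
  unname(out)
}

# external-table axis -> event-attribute name used by subgroup filters
axis_to_attribute <- function(axis) {
  switch(axis,
         age_band = "age_band_at_event",
         union = "union_at_event",
         parity = "parity_cat",
         axis)
}

#' Completeness table by subgroup
#'
#' Builds a percent-reported table shaped like the published comparisons:
#' one row per subgroup category (plus a Total row), with the weighted
#' survey count, the windowed external count, percent reported, the 95%
#' interval and the unweighted event count.
#'
#' @inheritParams weighted_event_count
#' @param external an [external_counts] table for the denominators.
#' @param by optional axis name in the external table (e.g. `"race"`,
#'   `"age_band"`, `"gestation_band"`); `NULL` gives the Total row only.
#' @param eligibility optional [eligibility_spec()] applied to both sides:
#'   excluded categories and ineligible event ages are removed from the
#'   numerator (event-exact) and from the denominators (via the year's
#'   category distribution), keeping the comparison frame-consistent.
#' @return data.frame with columns `group`, `category`, `weighted_count`,
#'   `external_count`, `percent`, `ci_low`, `ci_high`, `unweighted_n`
#'   (percent columns display-rounded with [round_half_up()] by
#'   `format_completeness_table()`; stored unrounded here).
#' @export
completeness_table <- function(cohort, window, external, outcome, mode,
                               by = NULL, eligibility = NULL) {
  rows <- list()
  add_row <- function(group, category, subgroup, axis, cat) {
    num <- weighted_event_count(cohort, window, outcome, mode, subgroup,
                                eligibility)
    den <- external_window_count(external, window, outcome, axis, cat,
                                 eligibility)
    pr <- percent_reported(num, den)
    data.frame(group = group, category = category,
               weighted_count = num$estimate, external_count = den,
               percent = pr$percent, ci_low = pr$ci_low,
               ci_high = pr$ci_high, unweighted_n = num$unweighted_n,
               stringsAsFactors = FALSE)
  }
  rows[[1]] <- add_row("total", "all", NULL, "total", "all")
  if (!is.null(by)) {
    cats <- sort(unique(external$category[external$axis == by &
                                            external$outcome == outcome]))
    attr_name <- axis_to_attribute(by)
    for (cl in cats) {
      rows[[length(rows) + 1L]] <- add_row(
        by, cl, stats::setNames(list(cl), attr_name), by, cl)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Display-round a completeness table like the published tables
#'
#' @param tab output of [completeness_table()].
#' @return the table with percent columns rounded to integers (half away
#'   from zero) and counts rounded to whole events.
#' @export
format_completeness_table <- function(tab) {
  tab$weighted_count <- round_half_up(tab$weighted_count)
  tab$external_count <- round_half_up(tab$external_count)
  for (col in c("percent", "ci_low", "ci_high")) {
    tab[[col]] <- round_half_up(tab[[col]])
  }
  tab
}

#' @export
print.weighted_total <- function(x, ...) {
  cat(sprintf(
    "<weighted_total> estimate %.1f (SE %.1f, design df %d, n = %d)\n",
    x$estimate, x$standard_error, x$design_df, x$unweighted_n))
  invisible(x)
}

#' @export
print.completeness_estimate <- function(x, ...) {
  cat(sprintf("<completeness_estimate> %g%% reported (95%% CI %g-%g)\n",
              round_half_up(x$percent), round_half_up(x$ci_low),
              round_half_up(x$ci_high)))
  invisible(x)
}
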