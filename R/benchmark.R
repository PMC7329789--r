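#' Linear interpolation of anchor-year totals
#'
#' Benchmark event totals are typically measured only in anchor years (for
#' instance, periodic provider-census rounds); interim annual totals are
#' obtained by piecewise-linear interpolation between adjacent anchors.
#' Interpolation is exact at the anchors and never extrapolates: a
#' requested year outside the anchor span is an error, since the published
#' interpolations this mirrors cover interior years only.
#'
#' @param anchors data.frame with numeric columns `year` (strictly
#'   increasing, at least two) and `total` (nonnegative).
#' @param years calendar years to evaluate.
#' @return named numeric vector, `years -> interpolated total`.
#' @export
#' @examples
#' interpolate_totals(data.frame(year = c(2004, 2008),
#'                               total = c(100, 200)), 2004:2008)
interpolate_totals <- function(anchors, years) {
  check_anchor_years(anchors$year)
  if (any(anchors$total < 0)) stop("anchor totals must be nonnegative")
  years <- as.integer(years)
  if (any(years < min(anchors$year) | years > max(anchors$year))) {
    bad <- years[years < min(anchors$year) | years > max(anchors$year)]
    stop(sprintf(
      "year(s) %s outside the anchor span %d-%d (no extrapolation)",
      paste(bad, collapse = ", "), min(anchors$year), max(anchors$year)))
  }
  out <- stats::approx(anchors$year, anchors$total, xout = years,
                       method = "linear", ties = "ordered")$y
  names(out) <- years
  out
}

#' Linear interpolation of anchor-round category distributions
#'
#' Category distributions (for instance, the demographic profile of
#' patients from periodic patient surveys) are interpolated category-wise
#' between anchor rounds and then renormalized to sum to 1 — category-wise
#' linear interpolation of proper distributions is already proper, but
#' renormalization guards the invariant against numerical drift.
#'
#' @param anchors data.frame with columns `year`, `category`, `proportion`;
#'   every anchor year must carry the same category set and proportions
#'   summing to 1 within 1e-9.
#' @param years calendar years to evaluate (within the anchor span).
#' @return named list, one named proportion vector per year.
#' @export
#' @examples
#' a <- data.frame(year = rep(c(2000, 2008), each = 2),
#'                 category = c("A", "B", "A", "B"),
#'                 proportion = c(0.4, 0.6, 0.6, 0.4))
#' interpolate_distributions(a, 2004)
interpolate_distributions <- function(anchors, years) {
  yrs <- sort(unique(anchors$year))
  check_anchor_years(yrs)
  cats <- NULL
  per_year <- split(anchors, anchors$year)
  for (y in names(per_year)) {
    a <- per_year[[y]]
    if (anyDuplicated(a$category)) {
      stop(sprintf("anchor year %s: duplicated category", y))
    }
    if (is.null(cats)) {
      cats <- sort(a$category)
    } else if (!identical(sort(a$category), cats)) {
      stop(sprintf(
        "anchor year %s: category set differs from other anchor rounds", y))
    }
    errs <- check_proportions(stats::setNames(a$proportion, a$category),
                              sprintf("anchor year %s", y))
    if (length(errs)) stop(paste(errs, collapse = "; "))
  }
  years <- as.integer(years)
  if (any(years < min(yrs) | years > max(yrs))) {
    stop(sprintf("year(s) outside the anchor span %d-%d (no extrapolation)",
                 min(yrs), max(yrs)))
  }
  out <- lapply(years, function(y) {
    p <- vapply(cats, function(cl) {
      sub <- anchors[anchors$category == cl, ]
      stats::approx(sub$year, sub$proportion, xout = y,
                    ties = "ordered")$y
    }, 0)
    p / sum(p)
  })
  names(out) <- years
  out
}

check_anchor_years <- function(years) {
  if (length(years) < 2L) {
    stop("need at least two anchor years for interpolation")
  }
  if (any(diff(years) <= 0)) {
    stop("anchor years must be strictly increasing")
  }
  invisible(years)
}

#' Apportion annual totals by interpolated category distributions
#'
#' `count(year, category) = total(year) * proportion(year, category)`, so
#' apportionment conserves each year's total exactly.
#'
#' @param totals named numeric vector, `year -> total` (e.g. from
#'   [interpolate_totals()]).
#' @param distributions either a named list `year -> named proportion
#'   vector` for one axis, or a named list of such lists, one per axis.
#' @param outcome outcome label for the resulting table.
#' @param axis axis name when `distributions` is a single-axis list.
#' @return an [external_counts] table with the per-year total rows and the
#'   apportioned category rows.
#' @export
#' @examples
#' apportion(c("2006" = 1000),
#'           list("2006" = c(A = 0.3, B = 0.7)), outcome = "abortion")
apportion <- function(totals, distributions, outcome, axis = "category") {
  if (length(distributions) && is.numeric(distributions[[1]])) {
    distributions <- stats::setNames(list(distributions), axis)
  }
  yrs <- names(totals)
  for (ax in names(distributions)) {
    if (!setequal(names(distributions[[ax]]), yrs)) {
      stop(sprintf(
        "axis '%s': distribution years do not match the totals' years", ax))
    }
  }
  rows <- list(data.frame(year = as.integer(yrs), outcome = outcome,
                          axis = "total", category = "all",
                          count = as.numeric(totals),
                          stringsAsFactors = FALSE))
  for (ax in names(distributions)) {
    for (y in yrs) {
      p <- distributions[[ax]][[y]]
      rows[[length(rows) + 1L]] <- data.frame(
        year = as.integer(y), outcome = outcome, axis = ax,
        category = names(p), count = as.numeric(totals[[y]]) * as.numeric(p),
        stringsAsFactors = FALSE)
    }
  }
  external_counts(do.call(rbind, rows))
}

#' Recall-window specification
#'
#' Maps each interview year to the calendar years its respondents report
#' on (each with a coverage fraction, default 1 for annual resolution) and
#' carries the mixing proportions with which interview-year cohorts are
#' pooled.
#'
#' `fixed_lookback(k)` gives interview year `y` the window
#' `y - k, ..., y - 1` — the "k years preceding the January of the
#' interview year" design. `fixed_calendar(first, last)` gives every
#' interview year the same fixed calendar span, as in designs that ask
#' about one common reference period.
#'
#' @param preset a window preset from [fixed_lookback()] or
#'   [fixed_calendar()].
#' @param interview_year_mix named numeric vector mapping interview year to
#'   its mixing proportion (sums to 1).
#' @return an object of class `window_spec`: list with `windows` (named
#'   list `interview year -> data.frame(year, coverage)`) and `mix`.
#' @export
#' @examples
#' w <- build_window(fixed_lookback(5), c("2010" = 1))
#' w$windows[["2010"]]$year  # 2005..2009
build_window <- function(preset, interview_year_mix) {
  errs <- check_proportions(interview_year_mix, "interview_year_mix")
  if (length(errs)) stop(paste(errs, collapse = "; "))
  iy <- as.integer(names(interview_year_mix))
  windows <- lapply(iy, function(y) {
    yrs <- switch(preset$type,
      fixed_lookback = seq.int(y - preset$k, y - 1L),
      fixed_calendar = seq.int(preset$first, preset$last),
      stop(sprintf("unknown window preset type '%s'", preset$type)))
    data.frame(year = yrs, coverage = 1)
  })
  names(windows) <- names(interview_year_mix)
  structure(list(windows = windows, mix = interview_year_mix),
            class = "window_spec")
}

#' @param k positive integer lookback length in years.
#' @rdname build_window
#' @export
fixed_lookback <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || k <= 0) {
    stop("lookback length k must be a positive integer")
  }
  list(type = "fixed_lookback", k = as.integer(k))
}

#' @param first,last first and last calendar year of the fixed window.
#' @rdname build_window
#' @export
fixed_calendar <- function(first, last) {
  if (first > last) stop("fixed_calendar: first year exceeds last year")
  list(type = "fixed_calendar", first = as.integer(first),
       last = as.integer(last))
}

#' Sampling-frame eligibility specification
#'
#' Describes which benchmark events are comparable with a survey's
#' sampling frame: an eligible age range at the event (applied through the
#' age-band axis of the external distribution, with fractional overlap for
#' partially covered bands) and category-exclusion rules on other axes
#' (for instance, dropping foreign-born women when the frame excluded
#' later immigrants).
#'
#' @param age_range optional `c(min, max)` eligible age at event, applied
#'   to every calendar year, or a named list `year -> c(min, max)`.
#' @param exclude optional named list `axis -> character vector of excluded
#'   categories`.
#' @return an object of class `eligibility_spec`.
#' @export
#' @examples
#' eligibility_spec(age_range = c(26, 31),
#'                  exclude = list(nativity = "foreign_born"))
eligibility_spec <- function(age_range = NULL, exclude = list()) {
  if (!is.null(age_range) && !is.list(age_range)) {
    if (length(age_range) != 2L || age_range[1] > age_range[2]) {
      stop("eligibility age_range must be c(min, max) with min <= max")
    }
  }
  if (is.list(age_range)) {
    for (y in names(age_range)) {
      r <- age_range[[y]]
      if (length(r) != 2L || r[1] > r[2]) {
        stop(sprintf("eligibility age_range for year %s is empty", y))
      }
    }
  }
  structure(list(age_range = age_range, exclude = exclude),
            class = "eligibility_spec")
}

#' Adjust external counts for recall window and frame eligibility
#'
#' The comparability-adjusted external count for one outcome is
#' \deqn{\sum_{c} m_c \sum_{y \in W_c} f_{cy} \, E(y)}
#' where \eqn{m_c} are interview-cohort mixing proportions, \eqn{W_c} the
#' cohort's window years, \eqn{f_{cy}} their coverage fractions and
#' \eqn{E(y)} the year's eligible count — the year total with excluded
#' categories and ineligible ages removed via that year's category
#' distribution. Exclusions on distinct axes are marginal distributions,
#' so their eligible shares combine multiplicatively (independence across
#' axes is assumed and documented). The adjustment is linear in the
#' table's counts.
#'
#' @param table an [external_counts] table covering all window years.
#' @param window a `window_spec` from [build_window()].
#' @param eligibility an optional [eligibility_spec()].
#' @param outcome outcome label to adjust.
#' @return scalar adjusted external count.
#' @export
adjust_external <- function(table, window, eligibility = NULL,
                            outcome = "abortion") {
  stopifnot(inherits(window, "window_spec"))
  all_years <- unique(unlist(lapply(window$windows, `[[`, "year")))
  have <- unique(table$year[table$axis == "total" &
                              table$outcome == outcome])
  missing_yrs <- setdiff(all_years, have)
  if (length(missing_yrs)) {
    stop(sprintf("window references year(s) %s absent from the table",
                 paste(sort(missing_yrs), collapse = ", ")))
  }
  elig_frac <- vapply(all_years, function(y) {
    eligible_fraction(table, y, outcome, eligibility)
  }, 0)
  names(elig_frac) <- all_years
  tot <- vapply(all_years, function(y) external_total(table, y, outcome), 0)
  names(tot) <- all_years
  out <- 0
  for (iy in names(window$windows)) {
    w <- window$windows[[iy]]
    out <- out + window$mix[[iy]] *
      sum(w$coverage * tot[as.character(w$year)] *
            elig_frac[as.character(w$year)])
  }
  unname(out)
}

# Fraction of a year's counts that remain after eligibility exclusions.
eligible_fraction <- function(table, year, outcome, eligibility) {
  if (is.null(eligibility)) return(1)
  tot <- external_total(table, year, outcome)
  if (tot == 0) return(1)
  frac <- 1
  for (ax in names(eligibility$exclude)) {
    sub <- table[table$axis == ax & table$year == year &
                   table$outcome == outcome, ]
    if (nrow(sub) == 0L) {
      stop(sprintf("eligibility exclusion on axis '%s': axis absent for year %d",
                   ax, year))
    }
    excl <- sum(sub$count[sub$category %in% eligibility$exclude[[ax]]])
    frac <- frac * (1 - excl / tot)
  }
  if (!is.null(eligibility$age_range)) {
    rng <- if (is.list(eligibility$age_range)) {
      eligibility$age_range[[as.character(year)]] %||%
        stop(sprintf("no eligible age range configured for year %d", year))
    } else {
      eligibility$age_range
    }
    sub <- table[table$axis == "age_band" & table$year == year &
                   table$outcome == outcome, ]
    if (nrow(sub) == 0L) {
      stop(sprintf("age eligibility requires an 'age_band' axis for year %d",
                   year))
    }
    share <- sum(sub$count * band_overlap_fraction(sub$category, rng)) / tot
    frac <- frac * share
  }
  frac
}

# Fraction of each age band (assumed uniform within band) lying inside the
# eligible range. Accepts open bands "<15" and "45+" produced by the truth
# tabulation.
band_overlap_fraction <- function(labels, rng) {
  vapply(labels, function(lab) {
    if (grepl("^<", lab)) {
      hi <- as.integer(sub("^<", "", lab)) - 1L
      lo <- 0L
    } else if (grepl("\\+$", lab)) {
      lo <- as.integer(sub("\\+$", "", lab))
      hi <- 120L
    } else {
      b <- parse_age_bands(lab)
      lo <- b$lo; hi <- b$hi
    }
    width <- hi - lo + 1L
    overlap <- max(0L, min(hi, rng[2]) - max(lo, rng[1]) + 1L)
    overlap / width
  }, 0, USE.NAMES = FALSE)
}
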