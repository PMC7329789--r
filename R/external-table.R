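#' External benchmark count table
#'
#' A long-format table of benchmark ("external") event counts by calendar
#' year, outcome, demographic axis and category — the gold-standard
#' denominator against which survey-reported counts are compared. Besides
#' per-category rows, each (year, outcome) carries a total row with
#' `axis == "total"`, `category == "all"`. For each (year, outcome, axis)
#' the category counts must sum to the year total.
#'
#' @param df data.frame with columns `year`, `outcome`, `axis`, `category`,
#'   `count`.
#' @param rel_tol relative tolerance for the category-sum invariant.
#' @return an object of class `external_counts` (a data.frame).
#' @export
#' @examples
#' df <- data.frame(
#'   year = 2010, outcome = "abortion",
#'   axis = c("total", "race", "race"),
#'   category = c("all", "white", "black"),
#'   count = c(100, 60, 40))
#' external_counts(df)
external_counts <- function(df, rel_tol = 1e-6) {
  req <- c("year", "outcome", "axis", "category", "count")
  if (!all(req %in% names(df))) {
    stop("external_counts: need columns ",
         paste(setdiff(req, names(df)), collapse = ", "))
  }
  df <- as.data.frame(df)[req]
  df$year <- as.integer(df$year)
  df$count <- as.numeric(df$count)
  if (any(df$count < 0)) stop("external_counts: negative count")
  tot <- df[df$axis == "total", ]
  key <- function(d) paste(d$year, d$outcome)
  for (ax in setdiff(unique(df$axis), "total")) {
    sub <- df[df$axis == ax, ]
    sums <- tapply(sub$count, key(sub), sum)
    tot_map <- tot$count[match(names(sums), key(tot))]
    bad <- is.na(tot_map) |
      abs(sums - tot_map) > rel_tol * pmax(1, abs(tot_map))
    if (any(bad)) {
      stop(sprintf(
        "external_counts: axis '%s' does not sum to the year total for %s",
        ax, paste(names(sums)[bad], collapse = "; ")))
    }
  }
  class(df) <- c("external_counts", "data.frame")
  df
}

#' Total external count for one year and outcome
#'
#' @param table an [external_counts] object.
#' @param year calendar year.
#' @param outcome outcome label.
#' @return scalar count.
#' @export
external_total <- function(table, year, outcome) {
  sel <- table$axis == "total" & table$year == year &
    table$outcome == outcome
  if (!any(sel)) {
    stop(sprintf("no external total for year %s, outcome '%s'",
                 year, outcome))
  }
  sum(table$count[sel])
}

#' Read / write external count tables
#'
#' Long-format delimited text with columns year, outcome, axis, category,
#' count.
#'
#' @param path file path.
#' @return for `read_external_counts`, an [external_counts] object.
#' @export
read_external_counts <- function(path) {
  external_counts(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @param table an [external_counts] object.
#' @rdname read_external_counts
#' @export
write_external_counts <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.external_counts <- function(x, ...) {
  yrs <- range(x$year)
  cat(sprintf("<external_counts> %d rows, years %d-%d, outcomes: %s\n",
              nrow(x), yrs[1], yrs[2],
              paste(unique(x$outcome), collapse = ", ")))
  NextMethod()
}
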