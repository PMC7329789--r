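#' Published weighted/external count pairs for three U.S. fertility surveys
#'
#' Weighted survey counts, adjusted external benchmark counts and the
#' percent-reported values (with 95% intervals) as published for the
#' NSFG 2006-2015 (by recall length and survey mode), the NLSY97 Round 16
#' (2007-2011 window, with a foreign-born exclusion variant) and Add
#' Health Wave 4 (2003-2007 window, with a non-high-school-graduate
#' exclusion variant). Every published percent is a deterministic
#' function of the two counts printed beside it, so these rows double as
#' worked examples for [percent_reported()] and the display rounding.
#'
#' @return data.frame with columns `survey`, `row`, `quantity`,
#'   `weighted_count`, `external_count`, `percent_printed`,
#'   `ci_low_printed`, `ci_high_printed`, `unweighted_n`.
#' @export
#' @examples
#' pc <- published_count_pairs()
#' with(pc[1, ], round_half_up(100 * weighted_count / external_count))
published_count_pairs <- function() {
  path <- system.file("extdata", "printed_counts.csv",
                      package = "underreport", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
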