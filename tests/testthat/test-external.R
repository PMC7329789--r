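test_that("totals interpolate linearly between anchors and exactly at them", {
  a <- data.frame(year = c(2004, 2008), total = c(100, 200))
  expect_equal(unname(interpolate_totals(a, 2006)), 150)
  expect_equal(unname(interpolate_totals(a, c(2004, 2008))), c(100, 200))
  # hand interpolation on the second segment of a three-anchor series
  b <- data.frame(year = c(2000, 2004, 2008), total = c(50, 90, 70))
  expect_equal(unname(interpolate_totals(b, 2006)), 80)
  expect_equal(unname(interpolate_totals(b, 2001)), 60)
})

test_that("interpolation never extrapolates and stays within adjacent anchors", {
  a <- data.frame(year = c(2000, 2004, 2008), total = c(50, 90, 70))
  expect_error(interpolate_totals(a, 1999), "outside the anchor span")
  expect_error(interpolate_totals(a, 2009), "no extrapolation")
  set.seed(1)
  for (rep in 1:20) {
    yrs <- sort(sample(1990:2020, 4))
    while (any(diff(yrs) == 0)) yrs <- sort(sample(1990:2020, 4))
    tot <- stats::runif(4, 0, 1000)
    anch <- data.frame(year = yrs, total = tot)
    for (y in seq(min(yrs), max(yrs))) {
      v <- unname(interpolate_totals(anch, y))
      seg <- findInterval(y, yrs, rightmost.closed = TRUE)
      expect_gte(v, min(tot[seg], tot[seg + 1]) - 1e-9)
      expect_lte(v, max(tot[seg], tot[seg + 1]) + 1e-9)
    }
  }
  expect_error(interpolate_totals(data.frame(year = 2000, total = 5), 2000),
               "at least two anchor years")
  expect_error(
    interpolate_totals(data.frame(year = c(2004, 2000),
                                  total = c(1, 2)), 2002),
    "strictly increasing")
})

test_that("distributions interpolate category-wise and stay proper", {
  a <- data.frame(year = rep(c(2000, 2008), each = 2),
                  category = c("A", "B", "A", "B"),
                  proportion = c(0.4, 0.6, 0.6, 0.4))
  mid <- interpolate_distributions(a, 2004)[["2004"]]
  expect_equal(mid, c(A = 0.5, B = 0.5))
  # identical anchors: constant in between
  cst <- data.frame(year = rep(c(2000, 2008), each = 2),
                    category = c("A", "B", "A", "B"),
                    proportion = c(0.3, 0.7, 0.3, 0.7))
  for (y in 2000:2008) {
    expect_equal(interpolate_distributions(cst, y)[[1]],
                 c(A = 0.3, B = 0.7))
  }
  # every output sums to one
  for (y in 2001:2007) {
    expect_equal(sum(interpolate_distributions(a, y)[[1]]), 1,
                 tolerance = 1e-9)
  }
})

test_that("mismatched anchor category sets are a schema error", {
  bad <- data.frame(year = c(2000, 2000, 2008, 2008, 2008),
                    category = c("A", "B", "A", "B", "C"),
                    proportion = c(0.4, 0.6, 0.3, 0.3, 0.4))
  expect_error(interpolate_distributions(bad, 2004),
               "category set differs")
})

test_that("apportionment multiplies and conserves totals", {
  tab <- apportion(c("2006" = 1000),
                   list("2006" = c(A = 0.3, B = 0.7, C = 0)),
                   outcome = "abortion", axis = "grp")
  expect_equal(tab$count[tab$category == "A"], 300)
  expect_equal(tab$count[tab$category == "B"], 700)
  # zero-proportion category carried, not dropped
  expect_true("C" %in% tab$category)
  expect_equal(tab$count[tab$category == "C"], 0)

  set.seed(4)
  yrs <- as.character(2001:2005)
  totals <- stats::setNames(stats::runif(5, 100, 5000), yrs)
  p <- stats::runif(4); p <- p / sum(p)
  dists <- stats::setNames(
    lapply(yrs, function(y) stats::setNames(p, letters[1:4])), yrs)
  tab <- apportion(totals, dists, outcome = "birth", axis = "grp")
  for (y in yrs) {
    cats <- tab$count[tab$axis == "grp" & tab$year == as.integer(y)]
    expect_equal(sum(cats), unname(totals[y]), tolerance = 1e-6)
  }
})

test_that("window presets expand to the documented calendar years", {
  w5 <- build_window(fixed_lookback(5), c("2010" = 1))
  expect_equal(w5$windows[["2010"]]$year, 2005:2009)
  w1 <- build_window(fixed_lookback(1), c("2010" = 1))
  expect_equal(w1$windows[["2010"]]$year, 2009)
  wc <- build_window(fixed_calendar(2007, 2011),
                     c("2013" = 0.5, "2014" = 0.5))
  expect_equal(wc$windows[["2013"]]$year, 2007:2011)
  expect_equal(wc$windows[["2014"]]$year, 2007:2011)
  expect_error(fixed_lookback(0), "positive")
  expect_error(build_window(fixed_lookback(5), c("2010" = 0.8)),
               "interview_year_mix")
})

test_that("adjust_external reduces to a plain sum without exclusions", {
  tab <- toy_totals_table(2005:2009, c(10, 20, 30, 40, 50))
  w <- build_window(fixed_lookback(5), c("2010" = 1))
  expect_equal(adjust_external(tab, w, outcome = "abortion"), 150)
  expect_error(
    adjust_external(tab, build_window(fixed_lookback(5), c("2011" = 1)),
                    outcome = "abortion"),
    "absent from the table")
})

test_that("category exclusions remove their proportional share", {
  rows <- do.call(rbind, lapply(2005:2009, function(y) {
    data.frame(year = y, outcome = "abortion",
               axis = c("total", "nativity", "nativity"),
               category = c("all", "us_born", "foreign_born"),
               count = c(100, 90, 10))
  }))
  tab <- external_counts(rows)
  w <- build_window(fixed_lookback(5), c("2010" = 1))
  elig <- eligibility_spec(exclude = list(nativity = "foreign_born"))
  expect_equal(adjust_external(tab, w, elig, outcome = "abortion"),
               0.9 * 500)
})

test_that("overlapping two-cohort windows average the single-cohort sums", {
  # hand computation on a three-year toy table:
  # windows 2008-2009 (cohort 2010) and 2009-2010 (cohort 2011),
  # counts 10, 20, 40 -> 30 and 60 -> mixed 50/50 gives 45
  tab <- toy_totals_table(2008:2010, c(10, 20, 40))
  w_mixed <- build_window(fixed_lookback(2),
                          c("2010" = 0.5, "2011" = 0.5))
  expect_equal(adjust_external(tab, w_mixed, outcome = "abortion"), 45)
  one <- adjust_external(tab, build_window(fixed_lookback(2),
                                           c("2010" = 1)), outcome = "abortion")
  two <- adjust_external(tab, build_window(fixed_lookback(2),
                                           c("2011" = 1)), outcome = "abortion")
  expect_equal(c(one, two), c(30, 60))
  expect_equal(mean(c(one, two)), 45)
})

test_that("adjust_external is linear in the table's counts", {
  coh <- generate_cohort(small_config(), seed = 17)
  tab <- coh$truth
  tab2 <- tab
  tab2$count <- 2 * tab2$count
  w <- build_window(fixed_lookback(5), c("2012" = 1))
  elig <- eligibility_spec(age_range = c(20, 40),
                           exclude = list(nativity = "foreign_born"))
  a1 <- adjust_external(tab, w, elig, outcome = "abortion")
  a2 <- adjust_external(external_counts(as.data.frame(tab2)), w, elig,
                        outcome = "abortion")
  expect_equal(a2, 2 * a1, tolerance = 1e-12)
})

test_that("age eligibility takes fractional band overlap", {
  rows <- data.frame(year = 2009, outcome = "abortion",
                     axis = c("total", "age_band", "age_band"),
                     category = c("all", "20-29", "30-39"),
                     count = c(100, 60, 40))
  tab <- external_counts(rows)
  w <- build_window(fixed_lookback(1), c("2010" = 1))
  # eligible 25-34: half of each 10-year band
  elig <- eligibility_spec(age_range = c(25, 34))
  expect_equal(adjust_external(tab, w, elig, outcome = "abortion"),
               0.5 * 60 + 0.5 * 40)
})
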