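test_that("unit weights count qualifying events; weights scale exactly", {
  coh <- manual_cohort(weights = rep(1, 8),
                       event_woman = c(1, 2, 3, 4, 5, 6),
                       event_year = c(2008, 2008, 2009, 2010, 2011, 2005))
  w <- build_window(fixed_lookback(4), c("2012" = 1))  # 2008..2011
  wt <- weighted_event_count(coh, w, "abortion")
  expect_equal(wt$estimate, 5)  # the 2005 event falls outside the window
  expect_equal(wt$unweighted_n, 5L)
  expect_equal(wt$design_df, 2L)  # 4 PSUs - 2 strata

  coh2 <- coh
  coh2$women$base_weight <- rep(2, 8)
  wt2 <- weighted_event_count(coh2, w, "abortion")
  expect_equal(wt2$estimate, 2 * wt$estimate)
  expect_equal(wt2$standard_error, 2 * wt$standard_error)
  expect_equal(wt2$unweighted_n, wt$unweighted_n)
})

test_that("a lone-PSU stratum raises an error naming the stratum", {
  coh <- manual_cohort(weights = rep(1, 8), event_woman = 1,
                       event_year = 2008)
  coh$women$stratum_id <- c(1, 1, 1, 1, 2, 2, 2, 2)
  coh$women$psu_id <- c(1, 2, 1, 2, 3, 3, 3, 3)  # stratum 2 has one PSU
  w <- build_window(fixed_lookback(4), c("2012" = 1))
  expect_error(weighted_event_count(coh, w, "abortion"),
               "stratum 2 contains a single PSU")
})

test_that("adding a reported event never decreases the estimate", {
  cfg <- small_config(reporting_model = constant_reporting(0.5))
  coh <- apply_reporting_model(generate_cohort(cfg, seed = 31))
  w <- build_window(fixed_lookback(5), c("2012" = 1))
  base <- weighted_event_count(coh, w, "abortion", mode = "ftf")
  # flag one additional unreported in-window abortion as reported
  ev <- coh$events
  cand <- which(ev$outcome == "abortion" & !ev$reported_ftf &
                  ev$end_year %in% 2007:2011)
  expect_gt(length(cand), 0)
  for (i in cand[seq_len(min(5, length(cand)))]) {
    coh2 <- coh
    coh2$events$reported_ftf[i] <- TRUE
    wt2 <- weighted_event_count(coh2, w, "abortion", mode = "ftf")
    expect_gt(wt2$estimate, base$estimate)
  }
})

test_that("frame exclusions drop events from the numerator exactly", {
  coh <- manual_cohort(weights = rep(1, 8),
                       event_woman = c(1, 2, 3, 4),
                       event_year = rep(2009, 4))
  coh$women$nativity <- c("foreign_born", "us_born", "us_born",
                          "foreign_born", rep("us_born", 4))
  w <- build_window(fixed_lookback(4), c("2012" = 1))
  elig <- eligibility_spec(exclude = list(nativity = "foreign_born"))
  all4 <- weighted_event_count(coh, w, "abortion")
  native <- weighted_event_count(coh, w, "abortion", eligibility = elig)
  expect_equal(all4$estimate, 4)
  expect_equal(native$estimate, 2)
  expect_equal(native$unweighted_n, 2L)
  # age-at-event restriction is event-exact on the numerator
  coh$events$age_at_event <- c(19L, 25L, 30L, 35L)
  aged <- weighted_event_count(
    coh, w, "abortion",
    eligibility = eligibility_spec(age_range = c(20, 31)))
  expect_equal(aged$estimate, 2)
})

test_that("percent_reported reproduces the published worked examples", {
  pc <- published_count_pairs()
  for (i in seq_len(nrow(pc))) {
    num <- structure(list(estimate = pc$weighted_count[i],
                          standard_error = 0, design_df = 100L,
                          unweighted_n = pc$unweighted_n[i]),
                     class = "weighted_total")
    est <- percent_reported(num, pc$external_count[i])
    expect_equal(round_half_up(est$percent), pc$percent_printed[i],
                 info = paste(pc$survey[i], pc$row[i], pc$quantity[i]))
  }
})

test_that("percent_reported identity, domain errors and interval shape", {
  num <- structure(list(estimate = 500, standard_error = 0,
                        design_df = 10L, unweighted_n = 50L),
                   class = "weighted_total")
  est <- percent_reported(num, 500)
  expect_equal(est$percent, 100)
  expect_equal(c(est$ci_low, est$ci_high), c(100, 100))
  expect_error(percent_reported(num, 0), "positive")
  expect_error(percent_reported(num, -3), "positive")
  num$standard_error <- 50
  est <- percent_reported(num, 500)
  expect_lt(est$ci_low, est$percent)
  expect_gt(est$ci_high, est$percent)
  # intervals are not truncated at 0 or 100
  est2 <- percent_reported(
    structure(list(estimate = 490, standard_error = 30),
              class = "weighted_total"), 500)
  expect_gt(est2$ci_high, 100)
})

test_that("percent_reported is scale-equivariant", {
  set.seed(8)
  for (rep in 1:10) {
    est <- stats::runif(1, 10, 1000)
    se <- stats::runif(1, 0, 100)
    ext <- stats::runif(1, 500, 5000)
    k <- stats::runif(1, 0.1, 50)
    a <- percent_reported(structure(list(estimate = est,
                                         standard_error = se),
                                    class = "weighted_total"), ext)
    b <- percent_reported(structure(list(estimate = k * est,
                                         standard_error = k * se),
                                    class = "weighted_total"), k * ext)
    expect_equal(a$percent, b$percent)
    expect_equal(a$ci_low, b$ci_low)
    expect_equal(a$ci_high, b$ci_high)
  }
})

test_that("display rounding is half away from zero", {
  expect_equal(round_half_up(c(40.09, 29.73, 88.52)), c(40, 30, 89))
  expect_equal(round_half_up(c(0.5, 1.5, -0.5, -1.5)), c(1, 2, -1, -2))
  expect_equal(round_half_up(104.84), 105)
})

test_that("the non-overlap rule matches the published subgroup contrasts", {
  ci <- function(p, lo, hi) list(percent = p, ci_low = lo, ci_high = hi)
  # face-to-face vs self-administered mode
  expect_true(compare_nonoverlap(ci(40, 36, 44), ci(72, 65, 80)))
  # Catholic vs no-religion respondents
  expect_true(compare_nonoverlap(ci(29, 22, 36), ci(47, 39, 54)))
  expect_false(compare_nonoverlap(ci(40, 36, 44), ci(40, 36, 44)))
  # touching endpoints count as overlap
  expect_false(compare_nonoverlap(ci(40, 36, 44), ci(48, 44, 52)))
  # order-symmetric
  expect_true(compare_nonoverlap(ci(72, 65, 80), ci(40, 36, 44)))
})

test_that("completeness tables cover subgroups with consistent denominators", {
  cfg <- small_config(reporting_model = constant_reporting(0.6))
  coh <- apply_reporting_model(generate_cohort(cfg, seed = 19))
  w <- build_window(fixed_lookback(5), c("2012" = 1))
  tab <- completeness_table(coh, w, coh$truth, "abortion", "ftf",
                            by = "race")
  expect_equal(tab$group[1], "total")
  cats <- tab[tab$group == "race", ]
  expect_setequal(cats$category,
                  unique(coh$truth$category[coh$truth$axis == "race"]))
  # subgroup external counts sum to the total row's denominator
  expect_equal(sum(cats$external_count), tab$external_count[1],
               tolerance = 1e-9)
  expect_true(all(tab$ci_low <= tab$percent & tab$percent <= tab$ci_high))
  fmt <- format_completeness_table(tab)
  expect_true(all(fmt$percent == round_half_up(tab$percent)))
})
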