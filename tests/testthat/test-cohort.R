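test_that("zero event rates yield a zero truth table", {
  rates <- default_event_rates()
  for (oc in names(rates)) rates[[oc]]$base <- 0
  rates$birth$base <- 0.05  # births still flow
  cfg <- small_config(annual_event_rates = rates)
  coh <- generate_cohort(cfg, seed = 3)
  ab <- coh$truth[coh$truth$outcome == "abortion" &
                    coh$truth$axis == "total", ]
  expect_true(all(ab$count == 0))
  expect_setequal(ab$year, cfg$event_years)
  expect_false(any(coh$events$outcome == "abortion"))
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- small_config()
  a <- generate_cohort(cfg, seed = 11)
  b <- generate_cohort(cfg, seed = 11)
  expect_identical(a, b)
  c <- generate_cohort(cfg, seed = 12)
  expect_false(identical(a$events, c$events))
  ra <- apply_reporting_model(a, seed = 5)
  rb <- apply_reporting_model(b, seed = 5)
  expect_identical(ra$events, rb$events)
})

test_that("true annual counts follow the binomial generating process", {
  # single stratum, single PSU, every woman exposed in every event year
  cfg <- cohort_config(
    n_strata = 1, psus_per_stratum = 1, women_per_psu = 10,
    pop_per_psu = 400,
    interview_years = c("2012" = 1),
    age_range = c(30L, 44L), age_bands = c("30-44" = 1),
    event_years = 2010L, min_event_age = 15L,
    annual_event_rates = list(abortion = list(base = 0.05)))
  r <- 0.05
  W <- 400  # woman-years at risk in 2010
  counts <- vapply(1:20, function(s) {
    coh <- generate_cohort(cfg, seed = s)
    external_total(coh$truth, 2010, "abortion")
  }, 0)
  sd_bin <- sqrt(W * r * (1 - r))
  expect_true(all(abs(counts - r * W) <= 4 * sd_bin))
  # pooled check is tighter
  expect_lt(abs(mean(counts) - r * W), 4 * sd_bin / sqrt(20))
})

test_that("weights are inverse inclusion probabilities calibrated to the superpopulation", {
  cfg <- small_config(weight_dispersion = 0)
  coh <- generate_cohort(cfg, seed = 2)
  N <- cfg$n_strata * cfg$psus_per_stratum * cfg$pop_per_psu
  expect_equal(sum(coh$women$base_weight), N, tolerance = 1e-9)
  expect_true(all(coh$women$base_weight ==
                    cfg$pop_per_psu / cfg$women_per_psu))
  # every (stratum, PSU) cell populated with the configured sample size
  tab <- table(coh$women$stratum_id, coh$women$psu_id)
  expect_true(all(tab[tab > 0] == cfg$women_per_psu))
  expect_equal(sum(tab > 0), cfg$n_strata * cfg$psus_per_stratum)

  # lognormal dispersion: still ratio-calibrated, no longer constant
  cfg2 <- small_config(weight_dispersion = 0.3)
  coh2 <- generate_cohort(cfg2, seed = 2)
  expect_equal(sum(coh2$women$base_weight), N, tolerance = 1e-9)
  expect_gt(stats::sd(coh2$women$base_weight), 0)
})

test_that("survey records only contain events that precede the interview", {
  cfg <- small_config(interview_years = c("2011" = 0.5, "2012" = 0.5),
                      event_years = 2006:2011)
  coh <- generate_cohort(cfg, seed = 9)
  wi <- match(coh$events$woman_id, coh$women$woman_id)
  t_ev <- coh$events$end_year * 12 + coh$events$end_month
  t_int <- coh$women$interview_year[wi] * 12 +
    coh$women$interview_month[wi]
  expect_true(all(t_ev < t_int))
  # but the truth keeps the superpopulation's full history
  expect_gt(sum(coh$truth$count[coh$truth$axis == "total"]),
            nrow(coh$events))
})

test_that("truth table margins are internally consistent", {
  coh <- generate_cohort(small_config(), seed = 21)
  tr <- coh$truth
  expect_s3_class(tr, "external_counts")
  for (ax in c("race", "age_band", "union", "parity")) {
    sub <- tr[tr$axis == ax, ]
    sums <- tapply(sub$count, paste(sub$year, sub$outcome), sum)
    tot <- tr[tr$axis == "total", ]
    tot_map <- tot$count[match(names(sums), paste(tot$year, tot$outcome))]
    expect_equal(as.numeric(sums), as.numeric(tot_map))
  }
  gest <- tr[tr$axis == "gestation_band", ]
  expect_true(all(gest$outcome == "abortion"))
})

test_that("degenerate reporting probabilities flag everything or nothing", {
  cfg <- small_config(reporting_model = c(constant_reporting(1, "ftf"),
                                          constant_reporting(0, "acasi")))
  coh <- apply_reporting_model(generate_cohort(cfg, seed = 4))
  expect_true(all(coh$events$reported_ftf))
  expect_false(any(coh$events$reported_acasi))
})

test_that("intercept-only reporting at 0.40 matches the binomial oracle", {
  cfg <- small_config(n_strata = 4, psus_per_stratum = 6,
                      women_per_psu = 50, pop_per_psu = 100,
                      reporting_model = constant_reporting(0.40))
  coh <- apply_reporting_model(generate_cohort(cfg, seed = 6), seed = 6)
  ab <- coh$events[coh$events$outcome == "abortion", ]
  n <- nrow(ab)
  expect_gt(n, 10)
  frac <- mean(ab$reported_ftf)
  expect_lt(abs(frac - 0.40), 4 * sqrt(0.4 * 0.6 / n))
})

test_that("reported flags exist only on true events (perfect specificity)", {
  for (s in 1:5) {
    cfg <- small_config()
    coh0 <- generate_cohort(cfg, seed = s)
    coh <- apply_reporting_model(coh0, seed = s)
    # reporting adds flag columns but never rows
    expect_identical(coh$events[names(coh0$events)], coh0$events)
    expect_true(all(c("reported_ftf", "reported_acasi") %in%
                      names(coh$events)))
  }
})

test_that("re-assigning an already-flagged mode is an error", {
  coh <- apply_reporting_model(generate_cohort(small_config(), seed = 1))
  expect_error(apply_reporting_model(coh), "already carry reported flags")
})

test_that("configuration errors name the offending field", {
  expect_error(
    cohort_config(category_mixes = utils::modifyList(
      default_category_mixes(), list(race = c(white = 0.5, black = 0.4)))),
    "category_mixes\\$race")
  expect_error(cohort_config(interview_years = c("2012" = 0.9)),
               "interview_years")
  expect_error(
    cohort_config(annual_event_rates = list(abortion = list(base = 1.5))),
    "annual_event_rates\\$abortion\\$base")
  # several violations reported together
  err <- tryCatch(
    cohort_config(interview_years = c("2012" = 0.9),
                  gestation_mix = c("<9" = 0.5)),
    error = conditionMessage)
  expect_match(err, "interview_years")
  expect_match(err, "gestation_mix")
})

test_that("reporting model referencing an unknown attribute errors", {
  cfg <- small_config(reporting_model = list(
    ftf = list(intercept = 0, terms = list(zodiac = c(aries = 1)))))
  coh <- generate_cohort(cfg, seed = 2)
  expect_error(apply_reporting_model(coh), "unknown attribute 'zodiac'")
})

test_that("cohort round-trips through its delimited text outputs", {
  coh <- apply_reporting_model(generate_cohort(small_config(), seed = 13))
  dir <- withr::local_tempdir()
  paths <- write_cohort(coh, dir)
  expect_true(all(file.exists(paths)))
  tr <- read_external_counts(file.path(dir, "external_counts.csv"))
  expect_equal(as.data.frame(tr), as.data.frame(coh$truth))
  ev <- utils::read.csv(file.path(dir, "events.csv"))
  expect_equal(nrow(ev), nrow(coh$events))
  expect_true(all(ev$woman_id %in%
                    utils::read.csv(file.path(dir, "women.csv"))$woman_id))
})
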