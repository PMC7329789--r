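# underreport

Reporting completeness of sensitive events in complex surveys.

Population surveys under-count stigmatized pregnancy outcomes — induced
abortion most of all — because respondents omit them. `underreport`
measures that under-reporting and its analytic consequences for surveys
with complex designs (stratified, clustered, weighted), for researchers
in demography, reproductive health and survey methodology:

* **Completeness estimation.** The weighted number of events reported in
  a recall window, `T̂ = Σ wᵢ xᵢ`, with a design-based standard error by
  stratified between-PSU (with-replacement) linearization, is compared to
  a fixed external benchmark count `E`:
  `R̂ = 100 · T̂ / E`, with 95% CI `100 · (T̂ ± 1.96 SE) / E` and a
  conservative non-overlapping-CI rule for subgroup contrasts.
* **Benchmark construction.** Annual external counts by subgroup are
  built from sparse anchor data — piecewise-linear interpolation of
  census totals, category-wise interpolation of patient-survey
  distributions, apportionment (`count = total × proportion`), recall
  windows (`fixed_lookback(k)` / `fixed_calendar(a, b)`), and
  frame-eligibility adjustments applied consistently to numerator and
  denominator.
* **Misclassification-bias Monte Carlo.** For a logistic model
  `logit P(Y=1|η) = β₀ + β₁η` observed through `Y*` with perfect
  specificity and sensitivity `logit P(Y*=1|Y=1,η) = α₀ + α₁η`, the
  package simulates the bias of `β̂₁` across grids of outcome prevalence
  and differential reporting `α₁`, and checks every point against the
  exact asymptotic oracle
  `bias = [logit(p₁s₁) − logit(p₀s₀)] − β₁`.
* **A synthetic cohort generator with known truth** — a full finite
  superpopulation with dated pregnancy events, mode-specific reporting,
  and an exact truth table — so every estimator is validated by
  parameter recovery without any restricted microdata.

## Worked example

```r
library(underreport)

cfg <- cohort_config()                    # 4 strata x 6 PSUs x 25 women (of 250)
coh <- generate_cohort(cfg, seed = 1)
coh <- apply_reporting_model(coh, seed = 2)
coh
#> <synthetic_cohort>
#>   600 women sampled (4 strata x 24 PSUs), 401 events on record
#>   truth table: 999 rows over years 2004-2012

w   <- build_window(fixed_lookback(5), cfg$interview_years)
num <- weighted_event_count(coh, w, "abortion", mode = "ftf")
num
#> <weighted_total> estimate 260.0 (SE 53.3, design df 20, n = 26)

den <- adjust_external(coh$truth, w, outcome = "abortion")   # 476
percent_reported(num, den)
#> <completeness_estimate> 55% reported (95% CI 33-77)
```

The cohort's face-to-face abortion sensitivity is 0.40 by configuration;
this single small replicate estimates 55% with a wide interval that
covers 40 — across 50 seeded replicates the 95% CI covers the true
value in well over 90% of runs (that recovery rate is asserted in the
test suite).

The bias study, on a reduced grid:

```r
sc <- bias_scenario(reps = 50, differential_grid = c(-0.5, 0, 0.5), seed = 1)
run_grid(sc)
#>   prevalence alpha1    s0    s1 mean_bias   mc_se analytic_bias
#> 1       0.08   -0.5 0.462 0.342   -0.4077 0.01525       -0.3682
#> 2       0.08    0.0 0.400 0.400   -0.0655 0.01585       -0.0567
#> 3       0.08    0.5 0.339 0.458    0.2649 0.01553        0.2566
#> 4       0.20   -0.5 0.457 0.338   -0.4880 0.01016       -0.4836
#> 5       0.20    0.0 0.400 0.400   -0.1440 0.01022       -0.1504
#> 6       0.20    0.5 0.342 0.462    0.1902 0.01119        0.1810
#> 7       0.50   -0.5 0.447 0.329   -0.8217 0.00659       -0.8198
#> 8       0.50    0.0 0.400 0.400   -0.4230 0.00774       -0.4261
#> 9       0.50    0.5 0.352 0.472   -0.0419 0.00680       -0.0388
```

Reading the `alpha1 = 0` rows: even *nondifferential* under-reporting
biases the estimated log odds toward the null, and more so at higher
outcome prevalence (−0.07 at 8% prevalence, −0.42 at 50%). Differential
reporting can push the estimate in either direction — at low prevalence
a positive `alpha1` of 0.5 *over*-states the association by +0.26
log-odds. The `analytic_bias` column is the closed-form large-sample
value the simulation is checked against.

## Pipeline and CLI

`run_pipeline()` chains simulate → benchmark → completeness → bias from
one configuration (YAML file, preset name, or list) and writes delimited
text tables plus a JSON manifest. A thin command-line wrapper ships at
`inst/cli/underreport.R`:

```sh
Rscript inst/cli/underreport.R all --preset nsfg_like --seed 1 --outdir out/
```

Presets `nsfg_like`, `nlsy_like` and `addhealth_like` encode the three
contrasting survey designs (cross-sectional five-year lookback with two
modes; fixed 2007–2011 calendar window with a foreign-born exclusion;
single-cohort 2003–2007 window with an education-based frame
sensitivity) purely as configuration.

## Documentation

The methods vignette (`vignettes/underreporting-methods.Rmd`) documents
the models, every tunable parameter and default, the numerical choices
(root-finding tolerances, rounding, separation handling, sub-seeding)
and what the synthetic generator does and does not emulate about real
survey data.
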