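---
title: "Measuring under-reporting of sensitive pregnancy outcomes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring under-reporting of sensitive pregnancy outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(underreport)
```

## The problem

Population surveys are the main source of individual-level data on
fertility experiences, but respondents under-report stigmatized pregnancy
outcomes — induced abortion most severely. When a near-complete external
census of events exists (a provider census for abortions, vital records
for births, population estimates for denominators), the completeness of
survey reporting can be measured directly: the weighted number of events
respondents report, divided by the external count of events that actually
occurred to the represented population over the same calendar window.

`underreport` implements that comparison end to end for complex
(stratified, clustered, weighted) survey designs, together with a Monte
Carlo study of what under-reporting does to regression estimates that use
the reported outcome. Because the restricted microdata such analyses run
on cannot be redistributed, the package ships a synthetic-cohort
generator with exactly known truth, so every estimator is validated by
parameter recovery rather than by fixture files.

## The completeness statistic

For a survey mode $m$ and outcome $o$, the estimator is

$$\widehat{R} \;=\; 100 \times \frac{\widehat{T}}{E}, \qquad
\widehat{T} = \sum_i w_i \, x_i,$$

where $x_i$ is the number of respondent $i$'s events of outcome $o$ that
fall inside her recall window and are reported in mode $m$, $w_i$ is her
design weight, and $E$ is the externally benchmarked count of events for
the same window and frame. The external count is treated as a fixed
gold-standard constant: the 95% interval
$100\,(\widehat{T} \pm 1.96\,\widehat{SE})/E$ reflects survey sampling
error only.

The variance of $\widehat{T}$ uses stratified with-replacement
(between-PSU) linearization: with PSU totals $T_{hj}$ in stratum $h$,

$$\widehat{V} = \sum_h \frac{n_h}{n_h-1} \sum_{j=1}^{n_h}
  \left(T_{hj} - \bar T_h\right)^2,$$

with design degrees of freedom $\sum_h n_h - H$. Every sampled woman
anchors her PSU total, so zero-event respondents contribute design
information. Numerical and convention choices:

* **z, not t.** Intervals use $z = 1.96$. Published completeness tables
  of this kind print symmetric intervals consistent with a normal
  critical value, and the design degrees of freedom in national surveys
  are large enough that the difference is immaterial.
* **No truncation.** Intervals are not clipped at 0 or 100; a subgroup
  interval such as 74–106 is meaningful under the fixed-denominator
  convention and is printed as is.
* **Display rounding** is to the nearest integer, half away from zero
  (40.09 → 40, 29.73 → 30, 88.52 → 89, 104.5 → 105). Stored values are
  never rounded; only `format_completeness_table()` rounds.
* **Lone-PSU strata are an error**, never silently collapsed or
  centered at the stratum mean — both workarounds change variances
  invisibly. The caller must fix the design specification.
* **Significance** between subgroups uses the conservative
  non-overlap rule (`compare_nonoverlap()`): intervals that merely touch
  count as overlapping, and no formal two-sample test is attempted.

`published_count_pairs()` bundles published weighted/external count pairs
from three national surveys; since every printed percent is a
deterministic function of the two counts beside it, these rows serve as
worked examples for the ratio and rounding conventions.

## Building external benchmark counts

External counts are rarely annual: provider censuses run every few
years, and patient-characteristic surveys even less often. The
`external_counts` machinery reconstructs annual subgroup counts from
sparse anchors:

1. `interpolate_totals()` — piecewise-linear interpolation of anchor-year
   totals; exact at anchors, **no extrapolation** (the published interim
   estimates this mirrors cover interior years only; a year outside the
   anchor span must itself be supplied as an anchor).
2. `interpolate_distributions()` — category-wise linear interpolation of
   anchor-round distributions, renormalized to sum to 1. Category-wise
   interpolation of proper distributions is already proper;
   renormalization is kept because apportionment requires exactly proper
   proportions and guards against numerical drift. Anchor rounds with
   differing category sets are a schema error, not silently unioned.
3. `apportion()` — `count(year, cat) = total(year) × p(year, cat)`;
   conservation of annual totals is exact and asserted by the
   `external_counts` validity check (1e-6 relative).
4. `build_window()` — recall windows as configuration:
   `fixed_lookback(k)` gives interview year $y$ the years
   $y-k \dots y-1$; `fixed_calendar(a, b)` gives every cohort the same
   span. Coverage fractions default to 1 (annual resolution); partial
   exposure of a calendar year can be expressed per year.
5. `adjust_external()` — the comparability adjustment:
   $\sum_c m_c \sum_{y \in W_c} f_{cy} E(y)$ over interview cohorts $c$
   with mixing proportions $m_c$. Cohort mixing proportions are a
   **required input**, not a default: whether pooled estimates weight
   interview cohorts by respondent counts or equally is an analytic
   choice the caller must make explicitly.

Frame eligibility (`eligibility_spec()`) removes events not represented
in a survey's sampling frame: category exclusions (e.g. foreign-born
women for a cohort enrolled before an immigration wave) and an eligible
age-at-event range. Age eligibility is applied through the age-band axis
of the external distribution — external data classify *events* by age at
event, not women — with fractional overlap for partially covered bands
under a uniform-within-band assumption. Exclusions on distinct axes
multiply, which assumes independence of the axes' marginals; this is the
usual approximation when only marginal distributions are published, and
it is exact whenever one side of the product is 0 or 1. In
`completeness_table()` the same eligibility is applied to *both* sides:
event-exactly to the survey numerator and distributionally to the
external denominator, keeping the comparison frame-consistent.

## The synthetic cohort generator

`generate_cohort()` realises a complete finite superpopulation — every
woman of every PSU — so the truth table is an exact tabulation, not an
expectation:

* **Design.** `n_strata × psus_per_stratum` PSUs, each representing
  `pop_per_psu` women of whom `women_per_psu` are sampled with equal
  probability. Base weights are inverse inclusion probabilities times
  optional lognormal noise (`weight_dispersion`), ratio-calibrated to the
  superpopulation total — emulating poststratification without a raking
  system. With dispersion 0 calibration is exact by construction.
* **Events** occur at month resolution (the surveys emulated record
  month and year; days are not modeled), one Bernoulli trial per
  woman–year–outcome at the configured annual rate, modulated by
  subgroup multipliers and an optional PSU-level random intercept
  (`psu_sigma`, default 0) that induces within-PSU correlation so the
  design-based variance estimator is non-trivially exercised. The
  default rates (births 0.060, abortions 0.017, miscarriages 0.012,
  stillbirths 0.0004 per woman-year) match recent U.S. levels for women
  aged 15–44.
* **Truth vs record.** The superpopulation keeps generating events after
  a woman's interview date; only events preceding her interview month
  enter her survey record. Truth counts for a calendar year are
  therefore independent of the interview-year mix — exactly how real
  benchmark counts behave — which makes the windowed completeness
  estimator unbiased even when overlapping multi-cohort recall windows
  include years some cohorts were interviewed in.
* **Attributes at event.** Age at event is deterministic back-dating
  from age at interview; union status at event is sticky to the
  interview value with probability `union_stability` (default 0.8),
  otherwise redrawn; parity before the event is counted from the
  woman's own generated birth history.
* **Reporting** (`apply_reporting_model()`) assigns each true event an
  independent Bernoulli reported flag per mode with probability
  `invlogit(intercept + term offsets)` over event- and woman-level
  attributes. Flags exist only on true events: perfect specificity holds
  by construction, no event is ever fabricated. The default two-mode
  model reports births at 0.98 in both modes and abortions at 0.40
  face-to-face versus 0.72 in the private self-administered mode — the
  contrast repeatedly documented for sensitive outcomes.

What the generator deliberately does **not** model, and hence what
passing tests cannot show about real data: telescoping (misdating events
into or out of the recall window), misreporting of one outcome as
another (e.g. abortions reported as miscarriages), item or unit
nonresponse and response-propensity selection, and day-level timing.
Completeness estimates on real surveys fold all of those in; recovery
tests here validate the estimator arithmetic, not the absence of those
mechanisms.

## The misclassification-bias Monte Carlo

A hypothetical study estimates how a binary characteristic $\eta$
changes the odds of having had an abortion:

$$\operatorname{logit} P(Y = 1 \mid \eta) = \beta_0 + \beta_1 \eta,$$

but only $Y^*$ is observed, with perfect specificity and sensitivity

$$\operatorname{logit} P(Y^* = 1 \mid Y = 1, \eta) = \alpha_0 + \alpha_1 \eta .$$

The default scenario (`bias_scenario()`) draws $n = 10{,}000$ women per
replicate with $P(\eta = 1) = 0.30$, $\beta_1 = 1$ (odds ratio 2.7),
overall sensitivity 0.40 among true cases, marginal outcome prevalences
$\{0.08, 0.20, 0.50\}$, and 50 replicates per grid point.

Design choices that the verbal description of such a study leaves open,
resolved here as follows:

* **The differential-reporting axis is log-odds** ($\alpha_1$), spanning
  $-1.5 \dots 1.5$ in steps of 0.25 by default. Reports map each
  $\alpha_1$ to the implied sensitivity pair $(s_0, s_1)$ for
  interpretability. No published numeric scale exists for this axis, so
  the grid is a documented package choice.
* **"Overall sensitivity" is marginal among true cases**: $\alpha_0$ is
  re-solved at every $\alpha_1$ so that
  $(1-w_1)\,s_0 + w_1 s_1 = 0.40$ with
  $w_1 = P(\eta = 1 \mid Y = 1)$, holding the overall reporting level
  fixed while the differential varies.
* **Intercepts are solved, not guessed.** Both $\beta_0$ (for the target
  marginal prevalence) and $\alpha_0$ are roots of strictly monotone
  maps, found by `uniroot` and polished by bisection to residuals below
  1e-10, then verified by plug-back in the tests.
* **$\eta$ is resampled every replicate** rather than holding group
  sizes fixed, matching a design that repeatedly samples whole
  respondents from a population.
* **$\hat\beta_1$ is the closed-form log odds ratio** of the 2×2 table
  of $Y^*$ by $\eta$ — the exact MLE of the saturated binary-covariate
  logistic model. An iterative `glm` fit is the cross-check in the test
  suite, never the implementation. Replicates with a zero margin cell
  (separation) are dropped and counted rather than Firth-corrected; at
  the default sample sizes separation is vanishingly rare, and dropping
  keeps the estimator faithful to a plain logistic fit. A grid point
  losing more than 10% of replicates is flagged in the output.
* **Sub-seeding.** Replicate $r$ at grid point $g$ derives its seed
  deterministically from (scenario seed, $g$, $r$), so any single
  replicate is reproducible in isolation and grids are byte-identical
  under a fixed seed.

The exact large-sample oracle: with perfect specificity,
$P(Y^* = 1 \mid \eta) = p_\eta s_\eta$, so the limit of $\hat\beta_1$ is
$\operatorname{logit}(p_1 s_1) - \operatorname{logit}(p_0 s_0)$ and

$$\text{bias} = \bigl[\operatorname{logit}(p_1 s_1) -
  \operatorname{logit}(p_0 s_0)\bigr] - \beta_1 .$$

Two consequences are assertable exactly and are asserted: the bias is 0
when $s_0 = s_1 = 1$, and nondifferential under-reporting
($\alpha_1 = 0$, $s < 1$) with $\beta_1 > 0$ gives strictly negative
bias — attenuation toward the null — at every prevalence. The Monte
Carlo means are required to agree with this oracle within 3 Monte Carlo
standard errors at every grid point.

```{r, eval = FALSE}
sc <- bias_scenario(reps = 200, seed = 1)
grid <- run_grid(sc)
plot_bias_grid(grid)  # one panel per prevalence, bias vs alpha1
```

## Problem sizes used in validation

The test suite and the acceptance script choose sizes so that binomial
and Monte Carlo tolerances are sharp while a full run stays comfortable
on one CPU: the default synthetic design is 4 strata × 6 PSUs × 25 women
sampled from 250 per PSU (6,000 superpopulation women over 9 event
years); recovery checks run 50 seeded replicates per reporting
probability; oracle-agreement checks use 200 replicates per grid point at
$n = 10{,}000$; the variance check compares the linearized SE against a
1,000-replicate Rao–Wu PSU bootstrap with a 15% band. The 50-replicate
default of `bias_scenario()` is the reporting convention of the design
it reproduces; validation deliberately scales replicates up, not down.

## Known limitations

* The apportionment inherits the independence of the anchor sources: a
  total and a distribution measured in different instruments are
  combined multiplicatively, and axis-by-axis exclusions assume
  independent marginals.
* The uniform-within-band age adjustment degrades when an age band is
  much wider than the true support of event ages inside it; choose band
  definitions at the resolution of the eligibility boundaries where
  possible.
* External counts carry no sampling error in the intervals by
  convention; if the benchmark itself undercounts (as provider censuses
  are known to, slightly), completeness is correspondingly
  *over*-estimated, and conclusions about under-reporting are
  conservative.
* The generator's reporting model is conditionally independent across
  events; correlated within-woman reporting (a woman who conceals one
  abortion likely conceals all) is not modeled, and would mainly widen
  design-based variances.
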