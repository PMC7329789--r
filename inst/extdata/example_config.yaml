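# Example run configuration for the underreport pipeline.
# Any field left out takes the documented default (see ?cohort_config,
# ?bias_scenario, ?underreport_preset). A `preset:` key may name a
# bundled preset to start from; keys given here override it.
seed: 1
cohort:
  n_strata: 4
  psus_per_stratum: 6
  women_per_psu: 25
  pop_per_psu: 250
  interview_years:
    "2012": 0.5
    "2013": 0.5
  age_range: [15, 44]
  age_bands:
    "15-19": 0.17
    "20-29": 0.34
    "30-44": 0.49
  annual_event_rates:
    birth: {base: 0.060}
    stillbirth: {base: 0.0004}
    miscarriage: {base: 0.012}
    abortion:
      base: 0.017
      multipliers:
        poverty: {lt100: 1.4, 100to199: 1.1, 200plus: 0.8}
  weight_dispersion: 0.1
  psu_sigma: 0.0
  reporting_model:
    ftf:
      intercept: 0.0
      terms:
        outcome: {birth: 3.89, stillbirth: 2.20, miscarriage: 0.85, abortion: -0.41}
    acasi:
      intercept: 0.0
      terms:
        outcome: {birth: 3.89, stillbirth: 2.20, miscarriage: 1.39, abortion: 0.94}
window:
  type: fixed_lookback
  k: 5
completeness:
  outcome: abortion
  modes: [ftf, acasi]
  by: [race, age_band]
bias:
  n: 10000
  p_eta: 0.30
  beta1: 1.0
  prevalence_targets: [0.08, 0.20, 0.50]
  overall_sensitivity: 0.40
  differential_grid: [-1.5, -1.0, -0.5, 0.0, 0.5, 1.0, 1.5]
  reps: 50
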