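# Reference configuration: the published base case.
#
# Every entry is {base, low, high, distribution}; bare numbers are also
# accepted and set the base value only.  Anything omitted falls back to
# the built-in defaults, so an empty file reproduces default_parameters().
# Distributions drive the probabilistic sensitivity analysis:
#   triangular - mode = base, bounds = range (cost parameters)
#   beta       - mean = base, sd = (high - low)/4 (probabilities,
#                proportions, utilities); a base sitting on a range
#                boundary (test sensitivity/specificity of 1) is drawn
#                from the boundary-mode beta with the opposite bound as
#                its 2.5% quantile
#   fixed      - never sampled (crizotinib price is scenario-analysed via
#                the PAP switch instead)

clinical:
  # overall-survival hazard ratio, chemotherapy vs supportive care; used
  # as a proportional-hazards factor to build the supportive-care PFS
  # curve followed by false-positive patients
  hr_chemo_vs_supportive:
    base: 0.77
    low: 0.71
    high: 0.83
    distribution: beta
  # per-cycle death probability in the progressed state (from the
  # 5.4-month median post-progression survival)
  p_death_progressed:
    base: 0.086
    low: 0.08
    high: 0.093
    distribution: beta
  alk_prevalence:
    base: 0.065
    low: 0.014
    high: 0.116
    distribution: beta
  # Mosteller BSA of the 65 kg / 164 cm reference patient (m2); sizes the
  # pemetrexed dose at 500 mg/m2
  body_surface_area:
    base: 1.72
    low: 1.5
    high: 1.9
    distribution: triangular
  # share of progressed patients receiving salvage chemotherapy
  salvage_uptake:
    base: 0.566
    low: 0.26
    high: 0.72
    distribution: beta
  post_progression_median_os:
    base: 5.4
    low: 5.4
    high: 5.4
    distribution: fixed
  # Weibull PFS curves, S(t) = exp(-scale * t^shape); time units are set
  # under run: below
  criz_weibull_scale:
    base: 0.0211
    low: 0.0211
    high: 0.0211
    distribution: fixed
  criz_weibull_shape:
    base: 1.5326
    low: 1.5326
    high: 1.5326
    distribution: fixed
  chemo_weibull_scale:
    base: 0.0663
    low: 0.0663
    high: 0.0663
    distribution: fixed
  chemo_weibull_shape:
    base: 0.8604
    low: 0.8604
    high: 0.8604
    distribution: fixed
tests:
  # both assays are published as perfectly concordant with a 0.95-1
  # confidence interval
  ngs_sensitivity:
    base: 1.0
    low: 0.95
    high: 1.0
    distribution: beta
  ngs_specificity:
    base: 1.0
    low: 0.95
    high: 1.0
    distribution: beta
  pcr_sensitivity:
    base: 1.0
    low: 0.95
    high: 1.0
    distribution: beta
  pcr_specificity:
    base: 1.0
    low: 0.95
    high: 1.0
    distribution: beta
  cost_test_ngs:
    base: 1014.49
    low: 869.57
    high: 1159.42
    distribution: triangular
  cost_test_pcr:
    base: 660.75
    low: 440.5
    high: 881.01
    distribution: triangular
costs:
  # 2016 US dollars throughout; deliberately not inflation-adjusted
  pemetrexed_per_500mg:
    base: 2083.97
    low: 857.14
    high: 2126.51
    distribution: triangular
  chemo_other_per_cycle:
    base: 518.4
    low: 388.8
    high: 648.0
    distribution: triangular
  # fixed in the PSA; the half-price low bound feeds the one-way analysis
  crizotinib_per_day:
    base: 238.1
    low: 119.05
    high: 238.1
    distribution: fixed
  followup_per_cycle:
    base: 55.6
    low: 41.7
    high: 69.4
    distribution: triangular
  salvage_per_cycle:
    base: 2352.7
    low: 1921.1
    high: 4383.3
    distribution: triangular
  # one-off cost attached to the death transition
  palliative_terminal:
    base: 2042.91
    low: 793.65
    high: 5456.19
    distribution: triangular
  supportive_per_cycle:
    base: 337.5
    low: 158.7
    high: 793.7
    distribution: triangular
  # serious-adverse-event management during the initial chemo cycles
  sae_initial_chemo_per_cycle:
    base: 507.4
    low: 189.7
    high: 825.0
    distribution: triangular
utilities:
  # +-25% ranges; the PFS upper bound is truncated at the utility ceiling
  u_pfs:
    base: 0.804
    low: 0.603
    high: 1.0
    distribution: beta
  u_progressed:
    base: 0.321
    low: 0.24075
    high: 0.40125
    distribution: beta
run:
  horizon_years: 10.0
  # calibrated conventions: 25-day cycles; chemo curve read in weeks,
  # crizotinib curve in months; 12 salvage cycles; PAP pays the first 84
  # days of crizotinib (see the package vignette for the calibration)
  cycle_days: 25.0
  days_per_month: 30.0
  annual_discount: 0.05
  wtp_per_qaly: 32000.0
  chemo_max_cycles: 4.0
  salvage_max_cycles: 12.0
  half_cycle_correction: no
  criz_time_unit: month
  chemo_time_unit: week
  pap:
    enabled: yes
    paid_days: 84.0
  # "positives" accrues the test cost within the crizotinib-treated
  # subcohorts (the convention the published totals follow); "all"
  # charges every tested patient
  test_cost_policy: positives
  pemetrexed_billing: vial
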