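# Base-case model inputs: two guideline arms for intravenous voriconazole
# administration, shared detection/harm/cost/QALY distributions, staff
# rates, user-testing resources and cohort settings (GBP, 2018 prices).
#
# Distribution schema: {family, params, truncation?}
#   dirichlet:     params = pseudo-counts per category
#   beta:          params = [shape1, shape2]
#   lognormal:     params = [mu, sigma] on the natural-log scale
#   normal:        params = [mean, sd]
#   deterministic: params = [value]
# truncation = [lower, upper] clamps draws after sampling.
arms:
  current:
    # no-error then error types 1-11; each error-type entry equals the
    # sum of its severity row below (0.1 prior per joint cell)
    node1_pseudo_counts: [26.3, 0.3, 0.3, 10.8, 0.3, 6.3, 27.3, 0.3, 3.3, 33.3, 0.3, 27.8]
    severity:  # rows = error types 1-11; columns = minor, moderate, severe
      - [0.1, 0.1, 0.1]
      - [0.1, 0.1, 0.1]
      - [5.1, 5.6, 0.1]
      - [0.1, 0.1, 0.1]
      - [0.1, 6.1, 0.1]
      - [0.1, 27.1, 0.1]
      - [0.1, 0.1, 0.1]
      - [0.1, 3.1, 0.1]
      - [4.1, 29.1, 0.1]
      - [0.1, 0.1, 0.1]
      - [19.1, 3.6, 5.1]
    admin_time:  # minutes per dose
      family: normal
      params: [13.3, 0.41]
      truncation: [0.0, .inf]
  user_tested:
    node1_pseudo_counts: [67.3, 0.3, 0.3, 4.3, 1.3, 0.3, 48.3, 0.3, 6.3, 11.3, 0.3, 3.3]
    severity:
      - [0.1, 0.1, 0.1]
      - [0.1, 0.1, 0.1]
      - [2.1, 2.1, 0.1]
      - [0.1, 1.1, 0.1]
      - [0.1, 0.1, 0.1]
      - [3.1, 45.1, 0.1]
      - [0.1, 0.1, 0.1]
      - [0.1, 6.1, 0.1]
      - [0.1, 11.1, 0.1]
      - [0.1, 0.1, 0.1]
      - [0.1, 2.1, 1.1]
    admin_time:
      family: normal
      params: [11.9, 0.31]
      truncation: [0.0, .inf]
shared:
  # risk ratio of an error remaining undetected after double-checking,
  # used directly as the node-2 probability, so clamped to <= 1;
  # lognormal derived from a random-effects 95% prediction interval
  p_undetected:
    family: lognormal
    params: [-0.25, 0.086]
    truncation: [0.0, 1.0]
  p_no_harm:
    family: beta
    params: [217.0, 23.0]
  cost_detected:  # GBP per error detected before administration
    family: lognormal
    params: [-1.29, 1.10]
  cost_pade:  # GBP treatment cost per preventable adverse drug event
    minor:
      family: lognormal
      params: [4.82, 0.14]
    moderate:
      family: lognormal
      params: [7.13, 0.07]
    severe:
      family: lognormal
      params: [7.52, 0.06]
  qaly_decrement:  # QALYs lost per pADE
    minor:
      family: normal
      params: [0.004, 0.0011]
      truncation: [0.0, .inf]
    moderate:
      family: normal
      params: [0.035, 0.0089]
      truncation: [0.0, .inf]
    severe:
      family: normal
      params: [3.50, 0.83]
      truncation: [0.0, .inf]
  staff_rates:  # GBP per hour
    pharmacist: 65.0
    nurse: 37.0
  user_testing:
    interview_minutes:  # per interview; pharmacist + nurse attend
      pilot:
        family: normal
        params: [24.0, 2.2]
        truncation: [0.0, .inf]
      round1:
        family: normal
        params: [29.0, 2.5]
        truncation: [0.0, .inf]
      round2:
        family: normal
        params: [23.0, 2.1]
        truncation: [0.0, .inf]
      round3:
        family: normal
        params: [20.0, 1.2]
        truncation: [0.0, .inf]
    analysis_minutes:  # per interview; pharmacist only
      pilot:
        family: normal
        params: [94.0, 6.1]
        truncation: [0.0, .inf]
      round1:
        family: normal
        params: [76.0, 3.5]
        truncation: [0.0, .inf]
      round2:
        family: normal
        params: [53.0, 6.9]
        truncation: [0.0, .inf]
      round3:
        family: normal
        params: [50.0, 2.2]
        truncation: [0.0, .inf]
    revision_minutes:  # per round; pharmacist only
      round1:
        family: normal
        params: [265.0, 20.0]
        truncation: [0.0, .inf]
      round2:
        family: normal
        params: [140.0, 11.0]
        truncation: [0.0, .inf]
      round3:
        family: normal
        params: [140.0, 11.0]
        truncation: [0.0, .inf]
    n_pilot: 4
    n_per_round: 10
    transcription_rate: 1.75  # GBP per spoken minute
    training_cost: 562.0      # GBP, one-off
    equipment_cost: 4.0       # GBP, one-off
cohort:
  doses_per_year: 4000
  horizon_years: 5
  discount_rate: 0.035
  wtp: 20000.0
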