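n_persons: 50000
seed: 20130101
first_year: 2006
last_year: 2014
study_year: 2013
p_female: 0.605
p_sex_missing: 2.6e-06
p_birth_year_missing: 6.9e-05
age_distribution:
  0-4: 0.03
  5-9: 0.032
  10-14: 0.034
  15-19: 0.038
  20-24: 0.045
  25-29: 0.05
  30-34: 0.052
  35-39: 0.055
  40-44: 0.062
  45-49: 0.075
  50-54: 0.085
  55-59: 0.082
  60-64: 0.07
  65-69: 0.062
  70-74: 0.068
  75-79: 0.075
  80-84: 0.05
  85+: 0.035
state_probs:
  BW: 0.131
  BY: 0.157
  BE: 0.043
  BB: 0.03
  HB: 0.008
  HH: 0.022
  HE: 0.075
  MV: 0.02
  NI: 0.096
  NW: 0.219
  RP: 0.049
  SL: 0.012
  SN: 0.05
  ST: 0.027
  SH: 0.035
  TH: 0.026
p_state_foreign: 0.0028
p_state_missing: 0.0045
enrollment:
  p_late_entry: 0.08
  p_early_exit: 0.03
  p_gap: 0.1
  gap_mean_days: 22.0
mortality:
  annual_base: 6.0e-05
  annual_growth: 0.083
disease:
  BREAST:
    hazard_q:
      0-4: 0.0
      5-9: 0.0
      10-14: 0.0
      15-19: 0.0
      20-24: 2.0e-05
      25-29: 5.0e-05
      30-34: 0.0001
      35-39: 0.00018
      40-44: 0.0003
      45-49: 0.00045
      50-54: 0.00055
      55-59: 0.0006
      60-64: 0.0007
      65-69: 0.00075
      70-74: 0.00075
      75-79: 0.0007
      80-84: 0.00065
      85+: 0.00055
    p_prevalent:
      0-4: 0.0
      5-9: 0.0
      10-14: 0.0
      15-19: 0.0
      20-24: 0.0008
      25-29: 0.002
      30-34: 0.004
      35-39: 0.0072
      40-44: 0.012
      45-49: 0.018
      50-54: 0.022
      55-59: 0.024
      60-64: 0.028
      65-69: 0.03
      70-74: 0.03
      75-79: 0.028
      80-84: 0.026
      85+: 0.022
    p_recurrence: 0.25
    recurrence_mean_latency_q: 16.0
    fatality_q: 0.012
    coding:
      p_index_coded: 0.92
      p_index_inpatient: 0.3
      p_followup_g: 0.85
      followup_quarters: 3
      p_ancillary: 0.08
      p_z_post: 0.25
      z_quarters: 12
      p_history_miscode: 0.08
      p_g_prevalent: 0.03
      p_z_prevalent: 0.15
      p_suspected_only: 0.01
      p_excluded_dx: 0.002
      p_surgery: 0.7
      surgery_max_delay_days: 120
      recurrence_surgery_factor: 0.5
      watchful_fraction: 0.0
      watchful_p_followup: 0.2
  PROSTATE:
    hazard_q:
      0-4: 0.0
      5-9: 0.0
      10-14: 0.0
      15-19: 0.0
      20-24: 0.0
      25-29: 0.0
      30-34: 0.0
      35-39: 0.0
      40-44: 5.0e-05
      45-49: 0.00015
      50-54: 0.00035
      55-59: 0.0006
      60-64: 0.0009
      65-69: 0.0012
      70-74: 0.0013
      75-79: 0.0012
      80-84: 0.001
      85+: 0.0007
    p_prevalent:
      0-4: 0.0
      5-9: 0.0
      10-14: 0.0
      15-19: 0.0
      20-24: 0.0
      25-29: 0.0
      30-34: 0.0
      35-39: 0.0
      40-44: 0.002
      45-49: 0.006
      50-54: 0.014
      55-59: 0.024
      60-64: 0.036
      65-69: 0.048
      70-74: 0.052
      75-79: 0.048
      80-84: 0.04
      85+: 0.028
    p_recurrence: 0.25
    recurrence_mean_latency_q: 16.0
    fatality_q: 0.01
    coding:
      p_index_coded: 0.92
      p_index_inpatient: 0.3
      p_followup_g: 0.85
      followup_quarters: 3
      p_ancillary: 0.08
      p_z_post: 0.25
      z_quarters: 12
      p_history_miscode: 0.08
      p_g_prevalent: 0.03
      p_z_prevalent: 0.15
      p_suspected_only: 0.01
      p_excluded_dx: 0.002
      p_surgery: 0.0
      surgery_max_delay_days: 120
      recurrence_surgery_factor: 0.5
      watchful_fraction: 0.25
      watchful_p_followup: 0.2
  COLORECTAL:
    hazard_q:
      0-4: 0.0
      5-9: 0.0
      10-14: 0.0
      15-19: 0.0
      20-24: 0.0
      25-29: 0.0
      30-34: 2.0e-05
      35-39: 3.0e-05
      40-44: 5.0e-05
      45-49: 9.0e-05
      50-54: 0.00015
      55-59: 0.00022
      60-64: 0.00032
      65-69: 0.00045
      70-74: 0.0006
      75-79: 0.00075
      80-84: 0.0009
      85+: 0.001
    p_prevalent:
      0-4: 0.0
      5-9: 0.0
      10-14: 0.0
      15-19: 0.0
      20-24: 0.0
      25-29: 0.0
      30-34: 0.0008
      35-39: 0.0012
      40-44: 0.002
      45-49: 0.0036
      50-54: 0.006
      55-59: 0.0088
      60-64: 0.0128
      65-69: 0.018
      70-74: 0.024
      75-79: 0.03
      80-84: 0.036
      85+: 0.04
    p_recurrence: 0.25
    recurrence_mean_latency_q: 16.0
    fatality_q: 0.035
    coding:
      p_index_coded: 0.92
      p_index_inpatient: 0.3
      p_followup_g: 0.85
      followup_quarters: 3
      p_ancillary: 0.08
      p_z_post: 0.25
      z_quarters: 12
      p_history_miscode: 0.08
      p_g_prevalent: 0.03
      p_z_prevalent: 0.15
      p_suspected_only: 0.008
      p_excluded_dx: 0.002
      p_surgery: 0.65
      surgery_max_delay_days: 120
      recurrence_surgery_factor: 0.5
      watchful_fraction: 0.0
      watchful_p_followup: 0.2
benign_dx_mean: 2.0
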