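schema_version: 1
dialect: text
econ:
  start_age: 65.0
  horizon: 30
  cycle_length: 1.0
  discount_rate_costs: 0.03
  discount_rate_effects: 0.03
  wtp: 50000.0
  half_cycle: no
population:
  share_scd: 0.53
  share_mci: 0.3
  share_mild_dem: 0.17
  amyloid_prev_scd: 0.31
  amyloid_prev_mci: 0.548
  amyloid_prev_dem: 0.841
accuracy:
  bbm_sensitivity: 0.89
  bbm_specificity: 0.69
  csf_sensitivity: 0.91
  csf_specificity: 0.89
policy:
  soc_referral_rate: 0.52
  bbm_positive_referral_rate: 1.0
natural_history:
  p_scd_to_mci_amypos: 0.41
  p_mci_to_mild_amypos: 0.22
  p_scd_to_mci_amyneg: 0.1
  p_mci_to_mild_amyneg: 0.05
  progression_odds_ratio: 5.89
treatment:
  effect: 0.27
  max_duration: 2
  annual_cost: 5000.0
  responder_fraction_amypos: 1.0
  responder_fraction_amyneg: 0.0
costs:
  phc_cost_scd: 959.0
  phc_cost_mci: 1896.0
  phc_cost_dem: 1896.0
  csf_exam_incl_mc_visit: 1940.0
  mc_visit: 524.0
  bbm_test: 200.0
  state_scd: 9180.0
  state_mci: 9180.0
  state_mild: 27014.0
  state_moderate: 30824.0
  state_severe: 35471.0
  state_mild_ltc: 81383.0
  state_moderate_ltc: 66849.0
  state_severe_ltc: 66977.0
utilities:
  u_scd_amyneg: 0.87
  u_scd_amypos: 0.86
  u_mci_amyneg: 0.71
  u_mci_amypos: 0.81
  u_mild: 0.74
  u_moderate: 0.59
  u_severe: 0.36
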