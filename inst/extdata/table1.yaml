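# Base-case parameter set for the T+I+B vs T+I cost-effectiveness model.
# All costs in USD per monthly cycle; medians in months; utilities are
# annual QALY weights.
settings:
  annual_discount_rate: 0.03
  wtp_threshold: 38136.26
  exchange_rate: 6.437
  cycle_length: 1
  horizon_cycles: 120
  termination_fraction: 0.99
  psa_iterations: 1000
arms:
  tib:
    name: "T+I+B"
    median_efs: 9
    median_os: 19
    drug_cost_per_cycle: 2803.73
    drug_cost_components:
      tmz: 343.75
      irt: 576.15
      bev: 1883.83
    second_line_cost_per_cycle: 233.11
    hospitalization_cost_per_cycle: 43.96
    ae_cost_per_cycle: 10.09
    tests_cost_per_cycle: 185.63
    max_treatment_cycles: 12
  ti:
    name: "T+I"
    median_efs: 6
    median_os: 13
    drug_cost_per_cycle: 919.90
    drug_cost_components:
      tmz: 343.75
      irt: 576.15
    second_line_cost_per_cycle: 305.67
    hospitalization_cost_per_cycle: 43.96
    ae_cost_per_cycle: 13.87
    tests_cost_per_cycle: 176.56
    max_treatment_cycles: 12
utilities:
  u_efs: 0.89
  u_pd: 0.73
  u_death: 0.0
dosing:
  tmz_dose: 50
  tmz_days: 5
  irt_dose: 50
  irt_days: 5
  bev_dose: 10
  bev_administrations_per_cycle: 2
default_weight_kg: 40
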