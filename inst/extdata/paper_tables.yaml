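costs:
  gas_per_mile:
    base: 0.16
    low: 0.12
    high: 0.2
  maintenance_per_mile:
    base: 0.05
    low: 0.04
    high: 0.06
  overhead_per_person:
    base: 1066.18
    low: 799.64
    high: 1332.73
  av_cost_per_person:
    base: 3471.0
    low: 2603.0
    high: 4339.0
  medical_cost_per_person:
    base: 1001.14
    low: 750.86
    high: 1251.43
  value_of_lost_life:
    base: 176482.98
    low: 132362.24
    high: 220603.73
  regulation_fee_per_person:
    base: 3204.58
    low: 2403.44
    high: 4005.73
utilities:
  utility_survivor: 0.68
  discount_rate: 0.03
  median_age: 37.8
  life_expectancy: 78.9
cohort:
  cycle_hours: 6.0
  cohort_size: 1000.0
  distance_to_hospital_miles: 2.5
  seats_per_vehicle: 4.0
schedules:
- arm_label: status_quo
  improvement: 0.0
  time_points_h:
  - 0.0
  - 6.0
  - 12.0
  - 18.0
  - 24.0
  cumulative_rescued:
  - 0.0
  - 0.42
  - 0.56
  - 0.94
  - 1.0
  rescued_survival:
  - 1.0
  - 0.96
  - 0.9
  - 0.84
  - 0.78
  trapped_survival:
  - 1.0
  - 0.6
  - 0.44
  - 0.38
  - 0.32
- arm_label: improvement_5
  improvement: 0.05
  time_points_h:
  - 0.0
  - 6.0
  - 12.0
  - 18.0
  - 24.0
  cumulative_rescued:
  - 0.0
  - 0.44
  - 0.58
  - 0.99
  - 1.0
  rescued_survival:
  - 1.0
  - 0.96
  - 0.9
  - 0.84
  - 0.78
  trapped_survival:
  - 1.0
  - 0.6
  - 0.44
  - 0.38
  - 0.32
- arm_label: improvement_10
  improvement: 0.1
  time_points_h:
  - 0.0
  - 6.0
  - 12.0
  - 18.0
  cumulative_rescued:
  - 0.0
  - 0.45
  - 0.59
  - 1.0
  rescued_survival:
  - 1.0
  - 0.96
  - 0.9
  - 0.84
  trapped_survival:
  - 1.0
  - 0.6
  - 0.44
  - 0.38
- arm_label: improvement_15
  improvement: 0.15
  time_points_h:
  - 0.0
  - 6.0
  - 12.0
  - 18.0
  cumulative_rescued:
  - 0.0
  - 0.47
  - 0.62
  - 1.0
  rescued_survival:
  - 1.0
  - 0.96
  - 0.9
  - 0.84
  trapped_survival:
  - 1.0
  - 0.6
  - 0.44
  - 0.38
config:
  rate_input: per_cycle
  ordering_rule: competing
  rescued_survival_mode: from_rescue
  productivity_loss_scope: trapped_deaths
  medical_cost_scope: rescued
  intervention_components:
  - av_program
  - regulation_fee
  regulation_fee_both_arms: no
  qaly_integer_years: yes
  half_cycle: no
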