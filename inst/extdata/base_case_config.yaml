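reference_arm_id: eve_exe
annual_discount_rate: 0.035
cycle_length: 1.0
horizon: 180.0
wtp_threshold: 36000.0
utilities:
  u_pre: 0.7733
  u_post: 0.4964
survival_spec:
  PFS:
    family: weibull
    params:
      shape: 1.3
      scale: 10.0
  OS:
    family: weibull
    params:
      shape: 1.3
      scale: 34.0
scenario_flags:
  half_cycle_correction: no
  discount_from_start: no
  apply_rdi: no
  fixed_post_progression_survival_months: ~
arms:
- arm_id: eve_exe
  reference: yes
  relative_dose_intensity: 0.87
  pre_progression_cycle_costs:
    drug_acquisition: 2447.75
    administration: 0.0
    pretreatment: 0.0
    lab_tests: 42.82
    monitoring: 52.34
    prophylaxis: 0.0
  post_progression_cycle_cost: 1057.41
  end_of_life_cost: 823.6
  hr_pfs:
  - label: reference
    hr: 1.0
  hr_os:
  - label: reference
    hr: 1.0
  ae_profile:
  - event: pneumonitis
    frequency: 0.03
    unit_cost: 1200.0
    disutility: -0.4
  - event: anemia
    frequency: 0.06
    unit_cost: 300.0
    disutility: -0.15
  - event: nausea
    frequency: 0.08
    unit_cost: 100.0
    disutility: -0.1
- arm_id: bev_pacl
  reference: no
  relative_dose_intensity: 0.86
  pre_progression_cycle_costs:
    drug_acquisition: 3806.42
    administration: 260.89
    pretreatment: 82.58
    lab_tests: 52.41
    monitoring: 52.34
    prophylaxis: 274.72
  post_progression_cycle_cost: 1057.41
  end_of_life_cost: 823.6
  hr_pfs:
  - label: indirect chain (synthetic)
    hr: 1.3
  hr_os:
  - label: indirect chain (synthetic)
    hr: 0.98
  ae_profile:
  - event: neutropenia
    frequency: 0.02
    unit_cost: 207.0
    disutility: -0.4
  - event: nausea
    frequency: 0.01
    unit_cost: 100.0
    disutility: -0.4
  - event: arthralgia
    frequency: 0.1
    unit_cost: 0.0
    disutility: -0.15
- arm_id: bev_cape
  reference: no
  relative_dose_intensity: 0.86
  pre_progression_cycle_costs:
    drug_acquisition: 3510.97
    administration: 115.95
    pretreatment: 36.69
    lab_tests: 48.25
    monitoring: 52.34
    prophylaxis: 416.77
  post_progression_cycle_cost: 1057.41
  end_of_life_cost: 823.6
  hr_pfs:
  - label: indirect chain (synthetic)
    hr: 1.49
  hr_os:
  - label: indirect chain (synthetic)
    hr: 0.96
  ae_profile:
  - event: vomiting
    frequency: 0.005
    unit_cost: 200.0
    disutility: -0.22
  - event: myalgia
    frequency: 0.01
    unit_cost: 0.0
    disutility: -0.2
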