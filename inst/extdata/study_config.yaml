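# Shipped study configuration: synthetic-cohort calibration targets,
# exposure constants, and Monte-Carlo settings. Values can be overridden
# per key; see ?generator_config and ?exposure_params for meanings/units.
generator:
  n_total: 50
  n_male: 25
  urine_mean: 20.38        # ug/L, uncorrected urinary 2-OHNAP
  urine_sd: 25.94
  urine_creat_mean: 16.65  # ug/g creatinine (calibration check only)
  urine_creat_sd: 21.98
  hair_mean: 8.16          # ng/g dw
  hair_sd: 7.62
  hair_nd_fraction: 0.12
  creatinine_mean: 144.326 # mg/dL
  creatinine_sd: 61.1
  bw_male_mean: 71.4       # kg
  bw_male_sd: 14.2
  bw_female_mean: 62.8
  bw_female_sd: 8.4
  age_mean: 46.62          # years, truncated to [18, 70]
  age_sd: 12.87
  bmi_mean: 25.16          # kg/m2
  bmi_sd: 4.2
  control_urine_mean: 0.18 # ug/g creatinine
  control_urine_sd: 0.09
  control_hair_mean: 0.7   # ng/g
  control_hair_sd: 0.08
  n_control: 4
  seed: 1
exposure:
  v_u: 2                   # L/day
  f: 1                     # urinary excretion fraction
  mw_parent: 128.17        # naphthalene, g/mol
  mw_metabolite: 144.17    # 2-OHNAP, g/mol
  cc_male: 23              # mg creatinine/kg-bw/day
  cc_female: 18
  rfd: 20                  # ug/kg-bw/day
  tef: 0.001
  csf: 7.3                 # (mg/kg-bw/day)^-1
simulation:
  n_iterations: 100000
  seed: 1
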