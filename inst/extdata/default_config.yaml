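# Default analysis configuration: published model estimates and the standard
# simulation settings (7.4 GBq per cycle, 4 cycles every 8 weeks).
poppk:
  cl: 4.95        # L/h
  vc: 21.59       # L
  q: 4.78         # L/h
  vp: 202.15      # L
  omega_cl: 0.41  # SD of log-normal IIV on CL
  omega_vc: 0.52  # SD of log-normal IIV on Vc
  rho: 0.70       # correlation of the CL and Vc random effects
  sigma_add: 0.40 # additive residual SD (concentration units)

dosimetry:        # adult model; set beta_study for the pooled model
  a_pop: 4.3      # Gy per cycle at 7.4 GBq / 99 mL/min
  b_pop: 0.66
  c_pop: -0.552
  beta_study: 0.0
  d_pop: 0.246
  e_pop: 0.597
  f_pop: -1.11
  b1: 0.515       # proportional residual SD, kidney
  b2: 0.675       # proportional residual SD, bone marrow
  ref_activity: 7.4
  ref_crcl: 99

grid:             # 8 activities x 30 CrCL values = 240 scenarios
  activities: {from: 1, to: 8, by: 1}
  crcl_values: {from: 35, to: 180, by: 5}
  n_subjects_per_cell: 500
  n_cycles: 4

trial_design:
  n_per_trial: [5, 10]
  n_trials: 500
  activity_per_cycle: 7.4
  n_cycles: 4

crcl_distribution:  # adolescent stand-in (cohort median 122.1, range 86-160)
  center: 122
  spread: 14.8
  lower: 86
  upper: 160

thresholds:
  kidney: [23, 29]   # Gy over 4 cycles
  bone_marrow: [2]

cohorts:
  n_adult: 47
  n_adolescent: 10

seed: 1
amount_scale: 1000 # MBq per GBq: concentrations carried in MBq/L
output_dir: "."
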