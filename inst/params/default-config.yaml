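# abqsp run configuration template.
# Loads in model units (0-16); reductions are fractions of suppressed
# deposition; seed drives cohort generation and measurement noise.
coupling:
  x0: 2
  delta: 0.025
  alpha: 0.002
  alpha_star: 0.002
  beta: 0.03
interventions:
  bace_low:  {name: BACE-I, reduction_x: 0.80, reduction_y: 0.60, dose_label: low}
  bace_high: {name: BACE-I, reduction_x: 0.90, reduction_y: 0.80, dose_label: high}
  gsi_low:   {name: GSI, reduction_x: 0.40, reduction_y: 0.20, dose_label: low}
  gsi_high:  {name: GSI, reduction_x: 0.50, reduction_y: 0.30, dose_label: high}
  sola_low:  {name: solanezumab, reduction_x: 0.05, reduction_y: 0.30, dose_label: low}
  sola_high: {name: solanezumab, reduction_x: 0.10, reduction_y: 0.50, dose_label: high}
cohort:
  "n": 20
  baseline: {"x": 8, "y": 8}
  genotype_freq: [0.25, 0.50, 0.25]   # APOE4-/-, APOE4+/-, APOE4+/+
  noise_sd: 0
trial:
  eval_weeks: [0, 12, 26, 52, 78]
seed: 1
out_dir: abqsp-output
log_level: info
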