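title: abqsp calibrated cognitive-surrogate parameters
description: Generated by calibrate_surrogate() from the default anchor set; regenerate
  with surrogate_params(refit = TRUE).
parameters:
  adas_ceiling: 70.0
  k: 0.114097030426153
  R50: 91.838228429538333
  link_nu: 0.2
  a_ben: 2.947885509602161
  a_def: 5.469230648922731
  s_glu: 0.8
  c_a7: 10.30502214758188
  s_a7: 2.368284796544261
  h_glu: 1.262602210486106
  adas_floor: 0.0
  acc_ceiling: 100.0
  acc_floor: 0.0
  ka: 0.042568284358427
  Ra50: 78.896201703381109
  c_syn: 0.060678460856578
  c_neu: 0.31339018992719
  c_m1: 0.173892785544439
  r_a7ach: 0.5
  sens_mci: 1.0
  a7_ad_scale: 0.15
  eval_weeks:
  - 0.0
  - 12.0
  - 26.0
  - 52.0
  - 78.0
  sens_weeks:
  - 0.390442550407295
  - 0.308745246367138
  - 0.191558558899865
  - 0.138687039443637
  - 0.451883248340677
  geno_ratio:
  - 1.11
  - 1.03
  - 1.01
  - 0.92
  - 0.9
  P0: 14.206199574540562
  syn0_ad: 0.9
  neu0_ad: 0.85
  syn_loss: 0.04
  neu_loss: 0.35
  tone_ad: 0.7
  tone_mci: 1.3
  mci_decrement: 3.0
provenance:
  anchors:
  - anchor: healthy_adas
    target: 4.5
    achieved: 4.5
    residual: 0.0
  - anchor: mci_zero_adas
    target: 4.1
    achieved: 4.1
    residual: -0.0
  - anchor: mci_region1_neg
    target: 7.4
    achieved: 7.42682
    residual: 0.02682
  - anchor: mci_region1_pos
    target: 10.4
    achieved: 10.218809
    residual: -0.181191
  - anchor: mci_region2_neg
    target: 7.8
    achieved: 7.690543
    residual: -0.109457
  - anchor: mci_region2_pos
    target: 10.699999999999999
    achieved: 12.065243000000001
    residual: 1.365243
  - anchor: mci_region3_neg
    target: 8.4
    achieved: 8.412775999999999
    residual: 0.012776
  - anchor: mci_region3_pos
    target: 14.199999999999999
    achieved: 13.396056
    residual: -0.803944
  - anchor: ad_baseline_het
    target: 21.0
    achieved: 21.0
    residual: -0.0
  - anchor: ad_worsening_78
    target: 9.25
    achieved: 9.25
    residual: -0.0
  - anchor: ad_week0_gap
    target: 2.0
    achieved: 2.0
    residual: -0.0
  - anchor: glu_slope_wk0
    target: 0.525
    achieved: 0.525
    residual: 0.0
  - anchor: glu_slope_wk12
    target: 0.65
    achieved: 0.65
    residual: -0.0
  - anchor: glu_slope_wk26
    target: 0.65
    achieved: 0.65
    residual: 0.0
  - anchor: glu_slope_wk52
    target: 0.4
    achieved: 0.4
    residual: 0.0
  - anchor: glu_slope_wk78
    target: 0.4
    achieved: 0.4
    residual: 0.0
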