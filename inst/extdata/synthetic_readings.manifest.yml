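wood_radius: 11.05
bt_max: 3.1
n_fissures: 12
depth_range:
- 2.0
- 2.67
halfwidth_range:
- 12.0
- 14.2
shape: triangular
seed: 20210114
name: deep_fissured
gauge_seed: 20210114
n_readings: 40
scheme: random
bias_cm: 0.0
true_solid_area_cm2: 157.6095931
true_bfi_area: 0.6422004
true_bfi_thickness: 0.662179
thickness_cv_pct: 37.3871119
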