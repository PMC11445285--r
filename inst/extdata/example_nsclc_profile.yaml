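name: NSCLC-like
n_patients: 20
lesion_count:
  type: nbinom
  mu: 3.5
  size: 3.0
  max: 15
organ_set:
- liver
- lung_left
- lung_right
- mediastinum
- abdomen
- pelvis
- skeleton
category_mixture:
  increasing: 0.3
  stable: 0.15
  decreasing: 0.35
  disappeared: 0.2
new_rate: 0.8
heterogeneous_fraction: 0.886
uptake_range:
- 3.0
- 10.0
uptake_noise_sd: 0.6
lesion_radius_range:
- 4.0
- 12.0
voxel_spacing:
- 4.0
- 4.0
- 4.0
volume_shape:
- 48
- 48
- 44
jitter_mm: 3.0
censoring_fraction: 0.2
true_beta:
  fraction_new: 0.5
  fraction_increasing: 0.45
  fraction_decreasing: -0.45
  count_disappeared: -0.3
  bl_global_suv_total: 0.25
baseline_hazard_rate: 0.0009205
tv_flip_time: ~
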