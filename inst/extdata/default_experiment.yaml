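# Default scan-rescan repeatability experiment: 23 patients, two sessions,
# 8 slices of 2 mm, 120x120 grid at 0.5 mm pixels.
seed: 1
cohort:
  n_patients: 23
  slices_per_patient: 8
  grid: 120
  pixel_spacing: 0.5
  slice_thickness: 2.0
  noise_sd: 0.08
  component_prevalence:
    fibrous: 1.0
    lipid: 0.43
    calcification: 0.87
    loose_matrix: 0.65
    ulceration: 0.0
    hemorrhage: 0.0
  rescan:
    through_plane_shift_slices: 1
    through_plane_jitter_slices: 0.35
    intensity_drift_sd: 0.05
    inplane_jitter_mm: 0.2
  observer:
    session_bias_sd: 0.08
    p_miss_small: 0.35
    small_area_threshold_mm2: 8
    boundary_jitter_px: 0.4
    reliable_contrast: 0.5
features:
  scales_mm: [0.1, 0.25, 0.5, 1.0, 2.0]
  derivative_orders: [0, 1, 2]
  normalization_roi_diameter_mm: 40
  scale_normalize: true
classifier:
  fibrous_prior: 0.55
  covariance_regularization: 1.0e-4
  postprocess_window: 3
stats:
  pair_inclusion: any_nonzero
  loa_multiplier: 1.96
  cr_multiplier: 2
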