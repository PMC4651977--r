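# Small demonstration run: 4 patients, 6 slices, 60x60 grid.
seed: 1
cohort:
  n_patients: 4
  slices_per_patient: 6
  grid: 60
  pixel_spacing: 0.5
  slice_thickness: 2.0
  noise_sd: 0.08
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
classifier:
  fibrous_prior: 0.55
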