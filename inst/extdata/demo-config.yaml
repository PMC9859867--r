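# Demo cohort: 58 synthetic subjects under the default CTP phantom protocol
# (2 s frames over 58 s, bolus arrival 8 s, venous lag 6 s, 5 HU noise).
n_subjects: 58
seed: 42
phantom:
  grid_shape: [64, 64, 32]
  voxel_size_mm: [3, 3, 3]
  noise_sd_hu: 5
extraction:
  smoothing_window: 3
alignment:
  grid_step_s: 0.1
quiet: true
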