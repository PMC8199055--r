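# Example kurtosig pipeline configuration.  Any key omitted here keeps its
# package default; unknown keys are rejected.
seed: 1
n_reference: 3
phantom:
  grid_shape: [64, 64, 24]
  voxel_size: [2.0, 2.0, 5.0]
  anat_voxel_size: [1.0, 1.0, 3.0]
  snr: 40
scheme:
  b_values: [0, 500, 1000, 1500, 2000, 2500]
  n_directions: 30
fit:
  sigma: 1.25        # pre-smoothing, in-plane voxels
  k_max: 3.0
  d_max: 5.0
  weighted: false
histogram:
  md_max: 3.5
  md_step: 0.05
  mk_max: 3.0
  mk_step: 0.02
signature:
  tau: 1.0e-5        # reference occupancy relative-frequency threshold
  dilate: 1
  min_cluster: 10
  bounds:
    md: [0.2, 3.0]
    mk: [0.1, 2.0]
evaluation:
  grid: dki          # or: anat
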