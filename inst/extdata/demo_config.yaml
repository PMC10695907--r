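# Bundled demo: 18 B1-like + 18 B2-like + 6 CN-like phantoms, fixed seed.
# Every analysis parameter is explicit; values are the package defaults.
cohort:
  base_seed: 42
  groups:
    - preset: B1-like
      n_specimens: 18
    - preset: B2-like
      n_specimens: 18
    - preset: CN-like
      n_specimens: 6
control_group: CN
segmentation:
  tolerance_k: 3.5
  neighborhood_radius: 2
  connectivity: 26
  min_component_voxels: 27
morphology:
  kernel: cube3
  iterations: 1
  background_connectivity: 6
stats:
  method: auto
  exact_cap: 200000
  alpha: 0.05
features:
  - volume_mm3
  - compression_score
  - inner_integrity
  - outer_integrity
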