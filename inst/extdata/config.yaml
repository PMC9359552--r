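# Default congestion-analysis configuration.
field:
  length_m: 159.5
  width_m: 128.8
  arc_radius_m: 50.0
clustering:
  eps: 7.5            # neighbourhood radius, metres
  min_additional: 3   # other players required within eps for core status
features:
  immediate: 5        # IPC / IDC radius, metres
  extended: 10        # EPC / EDC radius, metres
  quadrant: 10        # quadrant-count radius, metres
  available_space: 10 # available-space disc radius, metres
rf:
  n_trees: 500
  max_depth: 10
  min_split: 50
  min_leaf: 5
  train_fraction: 0.8
  seed: 1
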