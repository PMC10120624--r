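# Demo synthetic cohort: 2 matched pairs, one layer, two sites per subject.
sim:
  n_pairs: 2
geometry:
  nx: 64
  ny: 64
  nz: 18
  z_offset: 6
layers: ["III"]
sites_per_layer: 2
seed: 7
measure_sum: true
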