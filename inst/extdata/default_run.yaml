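# Default desk-scale validation run: i.i.d. random fields through the
# percolation and finite-size-scaling stages (no simulation).
stages: [synth, percolate, collapse]
seed: 1
synth:
  sizes: [32, 48, 64]
  n_fields: 24
percolate:
  p_min: 0.40
  p_max: 0.80
  p_step: 0.01
  connectivity: face4
collapse:
  n_boot: 0

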