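# Full-scale study configuration: 400 cells on a 320 x 320 periodic box
# (analysis lattice 321 x 321), subsystem sizes 20..100, percentile
# thresholding of the time-averaged isotropic stress.  This reproduces the
# published protocol's problem sizes; running it needs cluster-scale
# compute and is not part of the test suite, but the configuration
# validates and the pipeline accepts it.
stages: [simulate, stress, structure, percolate, collapse]
seed: 1
simulate:
  params:
    "N": 400
    R0: 8
    grid: [320, 320, 24]
    n_sim: 20000
    n_relax: 2000
  record_every: 5
  stress_every: 5
percolate:
  p_min: 0.30
  p_max: 0.90
  p_step: 0.005
  ells: [20, 40, 60, 80, 100]
  connectivity: face4
collapse:
  n_boot: 200

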