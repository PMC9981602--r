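# Small profile for quick end-to-end runs and continuous testing:
# 10 replicates, B = 200 resampling replicates.
seed: 42
design:
  n_replicates: 10
  age_min: 5
  age_max: 60
  qualities: ["90", "95", "100"]
analysis:
  B: 200
  tie_method: efron
  reference: "100"
  reference_n_per_cell: 30
io:
  out_dir: parastage_test_run
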