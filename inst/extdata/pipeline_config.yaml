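# Small demonstration configuration for the end-to-end synthetic pipeline.
# Sizes are reduced relative to the package defaults so a full run finishes
# in well under a minute; every stage still executes.
seed: 1
phantom_g: [0.0, 0.5, 1.0]
phantom_noise_sigma: 0.0
n_per_group:
  NC: 40
  MCI: 40
  AD: 40
retest_n: 15
feature_sets: ["FA", "FA+ALPS_Bi"]
n_repeats: 10
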