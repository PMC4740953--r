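# Example run configuration for the hlba pipeline CLI.
# Fields mirror cohort_config() and sampler_config().
cohort:
  n_mdd: 26
  n_hcl: 37
  n_face: 60
  n_oval: 20
  seed: 1
sampler:
  n_chains: 20
  n_samples: 5000
  burn_in: 2500
  migration_prob: 0.1
  seed: 1
min_rt: 0.150
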