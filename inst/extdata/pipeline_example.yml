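# Example pipeline configuration (see read_pipeline_config())
seed: 1
fraction: 0.75
states: [in_shell, de_shelled, granules]
chains: [Original, SG, SNV, MSC, "SG + SNV"]
generator:
  n_samples: 210
  fat_mean: 54.63
  fat_sd: 11.2
  fat_min: 40.85
  fat_max: 75.43
screening:
  md_confidence: 0.95
  residual_multiplier: 2.5
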