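{
  "comment": "Detectable-IBD graph feature battery, reference configuration at desk scale (50 Shapiro-Wilk batches of 500 replicates; minutes).",
  "diploid": 2000,
  "size_diploid": 100000,
  "w": 0.03,
  "mode": "overlap",
  "batch_size": 500,
  "n_batches": 50,
  "alpha": 0.05
}
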