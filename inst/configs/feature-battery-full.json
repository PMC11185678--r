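{
  "comment": "Detectable-IBD graph feature battery at study scale (250 batches of 500 = 125000 replicates; long-running, hours on one core).",
  "diploid": 2000,
  "size_diploid": 100000,
  "w": 0.03,
  "mode": "overlap",
  "batch_size": 500,
  "n_batches": 250,
  "alpha": 0.05
}
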