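{
  "comment": "Two-sample IBD-rate difference battery at desk scale (30 batches of 500; ~minutes).",
  "diploid": 5000,
  "size_diploid": 100000,
  "w": 0.03,
  "mode": "overlap",
  "batch_size": 500,
  "n_batches": 30,
  "alpha": 0.05
}
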