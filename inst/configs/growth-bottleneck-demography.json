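{
  "comment": "Example piecewise demography: large recent size, bottleneck, small ancient size (diploid units; doubled internally).",
  "epochs": [
    { "start_gen": 0, "size_diploid": 1000000 },
    { "start_gen": 100, "size_diploid": 50000 },
    { "start_gen": 300, "size_diploid": 10000 }
  ]
}
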