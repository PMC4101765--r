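{
  "out": ".",
  "seed": 1,
  "data": "/nonexistent.tsv",
  "lambda_o": 8.48,
  "bootstrap": 1000,
  "config_hash": "3243e534"
}
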