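{
  "c": 19.4117063993681,
  "anchor": 13,
  "seed": 42,
  "n_pairs": 10000,
  "raw_median": 0.669698981250984
}
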