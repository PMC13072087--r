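{
  "seed": 20,
  "sim_params": {
    "n_species": 100,
    "locality_range": [2, 500]
  }
}
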