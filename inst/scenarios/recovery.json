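{
  "name": "recovery",
  "population": {
    "n_subjects": 300,
    "w_dist": "uniform"
  },
  "estimation": { "estimator": "hierarchical" },
  "experiments": { "reliability": true, "recovery": true }
}
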