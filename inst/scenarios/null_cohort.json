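{
  "name": "null_cohort",
  "population": {
    "n_subjects": 200,
    "agent_kind": "uniform_random"
  },
  "estimation": { "estimator": "pointwise" },
  "experiments": { "reliability": false, "recovery": false }
}
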