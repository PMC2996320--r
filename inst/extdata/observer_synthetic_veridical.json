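{
  "true_map": {
    "LOW": {
      "tau": 5,
      "beta": 2
    },
    "MED": {
      "tau": 6,
      "beta": 2
    },
    "HIGH": {
      "tau": 7.2,
      "beta": 2
    }
  },
  "subjective_map": {
    "LOW": {
      "tau": 5,
      "beta": 2
    },
    "MED": {
      "tau": 6,
      "beta": 2
    },
    "HIGH": {
      "tau": 7.2,
      "beta": 2
    }
  },
  "rule": "subjective_prob",
  "noise": 20,
  "semiorder_threshold": 2,
  "transforms": null,
  "lapse": 0,
  "seed": 1
}
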