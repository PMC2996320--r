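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
  "rule": "transform",
  "noise": 10,
  "semiorder_threshold": 2,
  "transforms": {
    "LOW.MED": {
      "intercept": -0.217094084574542,
      "slope": 1.25992104989487
    },
    "MED.HIGH": {
      "intercept": -0.264483295034894,
      "slope": 1.25992104989487
    },
    "HIGH.LOW": {
      "intercept": -0.858837175877111,
      "slope": 1.25992104989487
    }
  },
  "lapse": 0,
  "seed": 1
}
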