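{
  "name": "M6NP_synthetic_placeholder",
  "reference": "failed_pul",
  "logits": {
    "iup": {
      "intercept": -4.0,
      "log_hcg1": 0.4,
      "log_ratio": 4.0,
      "log_ratio_sq": -0.8
    },
    "ep": {
      "intercept": 1.0,
      "log_hcg1": -0.35,
      "log_ratio": 0.3,
      "log_ratio_sq": -1.2
    }
  }
}
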