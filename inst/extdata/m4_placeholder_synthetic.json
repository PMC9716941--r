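{
  "name": "M4_synthetic_placeholder",
  "reference": "failed_pul",
  "logits": {
    "iup": {
      "intercept": -5.2,
      "log_hcg1": 0.5,
      "log_ratio": 5.2,
      "log_ratio_sq": -1.0
    },
    "ep": {
      "intercept": 0.4,
      "log_hcg1": -0.4,
      "log_ratio": 0.4,
      "log_ratio_sq": -1.6
    }
  }
}
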