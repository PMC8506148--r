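{
  "TOYCYP": {
    "rule_kind": "activity_interval",
    "normal_interval": [
      2,
      null
    ]
  }
}
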