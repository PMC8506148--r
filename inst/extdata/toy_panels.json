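{
  "tests": [
    {
      "name": "toy_star2_only",
      "targets": {
        "TOYCYP": "rs000002"
      },
      "lab": "toy"
    },
    {
      "name": "toy_full",
      "targets": {
        "TOYCYP": ["rs000002", "rs000003"]
      },
      "lab": "toy"
    }
  ]
}
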