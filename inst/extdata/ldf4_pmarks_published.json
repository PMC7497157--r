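[
  {
    "probability_level": 0.8,
    "pmark_F": -0.45,
    "pmark_M": 0.45,
    "n_boot": 1000,
    "seed": null,
    "method": "published",
    "model_ref": "LDF4"
  },
  {
    "probability_level": 0.9,
    "pmark_F": -0.76,
    "pmark_M": 0.76,
    "n_boot": 1000,
    "seed": null,
    "method": "published",
    "model_ref": "LDF4"
  },
  {
    "probability_level": 0.95,
    "pmark_F": -0.99,
    "pmark_M": 0.99,
    "n_boot": 1000,
    "seed": null,
    "method": "published",
    "model_ref": "LDF4"
  }
]
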