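{
  "model_kind": "lda",
  "variables": ["head_diameter", "epicondylar_breadth"],
  "coefficients": {
    "head_diameter": 0.3381,
    "epicondylar_breadth": 0.06205
  },
  "intercept": -19.07,
  "score_mean_F": null,
  "score_mean_M": null,
  "priors": {"F": 0.5, "M": 0.5},
  "n_F": 48,
  "n_M": 36,
  "metadata": {
    "name": "LDF4",
    "source": "published humeral discriminant equation (rounded coefficients as printed)",
    "population": "Middenbeemster reference series, 84 adults",
    "scaling": "unit pooled within-group score variance",
    "note": "equation-only publication: no fitted score means, so posteriors are unavailable; classify by sign or with the published PMarks",
    "units": "mm"
  }
}
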