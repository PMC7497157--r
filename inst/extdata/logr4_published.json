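{
  "model_kind": "logr",
  "variables": ["head_diameter", "epicondylar_breadth"],
  "coefficients": {
    "head_diameter": -0.8329,
    "epicondylar_breadth": -0.09285
  },
  "intercept": 43.42,
  "coded_one_sex": "F",
  "log_likelihood": -14.93,
  "aic": 35.87,
  "n": 84,
  "n_F": 48,
  "n_M": 36,
  "converged": true,
  "metadata": {
    "name": "LogR4",
    "source": "published humeral logistic equation (rounded coefficients as printed)",
    "population": "Middenbeemster reference series, 84 adults",
    "note": "returns P(Female) directly; P(Male) = 1 - P(Female)",
    "units": "mm"
  }
}
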