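{
  "schema_version": 1,
  "models": [
    {
      "id": "pst_published_norms_v1",
      "test": "pst",
      "coefficients": {
        "intercept": 65.2217,
        "age": -0.4591,
        "nonlinear_age": -0.0053,
        "education": 0.7999,
        "sex": -2.2132,
        "race": -4.0893
      },
      "rmse": 8.958,
      "nonlinear": "centered_quadratic",
      "constant": 50.26714
    },
    {
      "id": "vmt_published_norms_v1",
      "test": "vmt",
      "coefficients": {
        "intercept": 58.8785,
        "age": -0.3118,
        "nonlinear_age": -0.0329,
        "education": 0.7152,
        "race": -5.6555
      },
      "rmse": 12.879,
      "nonlinear": "knot_quadratic",
      "constant": 71
    }
  ]
}
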