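{
  "coefficients": {
    "t_dry": 0.752,
    "t_wet": 0.686,
    "t_globe": 0.774,
    "v_air": 0.244,
    "metabolism": 0.491,
    "clo": 0.387
  },
  "norm_min": {
    "t_dry": 21.97,
    "t_wet": 12.1,
    "t_globe": 23.4,
    "v_air": 0,
    "metabolism": 130,
    "clo": 0.5
  },
  "norm_range": {
    "t_dry": 26.23,
    "t_wet": 25.47,
    "t_globe": 39.3,
    "v_air": 4.2,
    "metabolism": 360,
    "clo": 0.85
  },
  "scale_factor": 10,
  "skin_temp_threshold": 35,
  "bands": [
    {
      "label": "Low",
      "lower": "-Inf"
    },
    {
      "label": "Moderate",
      "lower": "12.02"
    },
    {
      "label": "High",
      "lower": "15.88"
    },
    {
      "label": "Very high",
      "lower": "17.56"
    }
  ]
}
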