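{
  "name": "frs",
  "version": "general-cvd-2008",
  "description": "Framingham-style general cardiovascular disease 10-year risk equation, sex-specific Cox form; cholesterol in mmol/L is converted to mg/dL via scale 38.67; blood-pressure coefficient split by antihypertensive treatment.",
  "strata": [
    {"stratum": "female", "s0": 0.95012, "lp_mean": 26.1931},
    {"stratum": "male",   "s0": 0.88936, "lp_mean": 23.9802}
  ]
}
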