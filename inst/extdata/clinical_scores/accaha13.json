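{
  "name": "accaha13",
  "version": "pooled-cohort-2013-white",
  "description": "Pooled-cohort-equation style 10-year atherosclerotic risk, sex-specific Cox form with ln(age) interactions; white-stratum coefficients are applied to cohorts without race information.",
  "strata": [
    {"stratum": "female", "s0": 0.9665, "lp_mean": -29.18},
    {"stratum": "male",   "s0": 0.9144, "lp_mean": 61.18}
  ]
}
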