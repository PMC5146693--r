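Cross-tabulations of 10-year CHD risk categories (0-7.5%, 7.5-10%, 10-20%,
20-100%) before vs after adding a genomic risk score to a clinical risk
score, separately for subjects with and without an incident CHD event
within 10 years. Counts are from published reclassification tables for a
large Finnish population cohort (FINRISK-style, n = 12,669 classified:
517 events, 12,152 non-events) and a Framingham-style cohort (n = 3,406).
Rows: old (clinical-score-only) category; columns cat1..cat4: new
(clinical + genomic) category. Used by reproduce_tables() to recompute
categorical NRI from counts alone.
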