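stratum	covariate	transform	scale	covariate2	transform2	scale2	condition	condition_value	coefficient
female	entry_age	log	1					NA	2.32888
female	tc	log	38.67					NA	1.20904
female	hdl	log	38.67					NA	-0.70833
female	sbp	log	1				bp_treatment	0	2.76157
female	sbp	log	1				bp_treatment	1	2.82263
female	smoking	identity	1					NA	0.52873
female	diabetes	identity	1					NA	0.69154
male	entry_age	log	1					NA	3.06117
male	tc	log	38.67					NA	1.1237
male	hdl	log	38.67					NA	-0.93263
male	sbp	log	1				bp_treatment	0	1.93303
male	sbp	log	1				bp_treatment	1	1.99881
male	smoking	identity	1					NA	0.65451
male	diabetes	identity	1					NA	0.57367
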