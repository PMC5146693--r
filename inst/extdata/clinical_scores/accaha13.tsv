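stratum	covariate	transform	scale	covariate2	transform2	scale2	condition	condition_value	coefficient
female	entry_age	log	1					NA	-29.799
female	entry_age	log	1	entry_age	log	1		NA	4.884
female	tc	log	38.67					NA	13.54
female	entry_age	log	1	tc	log	38.67		NA	-3.114
female	hdl	log	38.67					NA	-13.578
female	entry_age	log	1	hdl	log	38.67		NA	3.149
female	sbp	log	1				bp_treatment	1	2.019
female	sbp	log	1				bp_treatment	0	1.957
female	smoking	identity	1					NA	7.574
female	entry_age	log	1	smoking	identity	1		NA	-1.665
female	diabetes	identity	1					NA	0.661
male	entry_age	log	1					NA	12.344
male	tc	log	38.67					NA	11.853
male	entry_age	log	1	tc	log	38.67		NA	-2.664
male	hdl	log	38.67					NA	-7.99
male	entry_age	log	1	hdl	log	38.67		NA	1.769
male	sbp	log	1				bp_treatment	1	1.797
male	sbp	log	1				bp_treatment	0	1.764
male	smoking	identity	1					NA	7.837
male	entry_age	log	1	smoking	identity	1		NA	-1.795
male	diabetes	identity	1					NA	0.658
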