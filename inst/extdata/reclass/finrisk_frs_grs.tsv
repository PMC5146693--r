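group	old_category	cat1	cat2	cat3	cat4
events	0-7.5%	110	21	19	2
events	7.5-10%	22	12	28	4
events	10-20%	22	24	108	78
events	20-100%	0	2	17	48
nonevents	0-7.5%	9456	197	119	4
nonevents	7.5-10%	346	178	195	17
nonevents	10-20%	277	266	659	220
nonevents	20-100%	1	12	97	108
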