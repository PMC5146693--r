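group	old_category	cat1	cat2	cat3	cat4
events	0-7.5%	67	6	0	0
events	7.5-10%	5	11	6	0
events	10-20%	2	5	43	4
events	20-100%	0	0	0	1
nonevents	0-7.5%	2415	82	4	0
nonevents	7.5-10%	117	154	77	1
nonevents	10-20%	9	69	296	15
nonevents	20-100%	0	0	5	12
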