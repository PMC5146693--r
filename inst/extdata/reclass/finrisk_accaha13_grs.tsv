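group	old_category	cat1	cat2	cat3	cat4
events	0-7.5%	118	16	17	1
events	7.5-10%	20	14	29	6
events	10-20%	15	29	104	60
events	20-100%	0	0	15	73
nonevents	0-7.5%	9470	195	127	6
nonevents	7.5-10%	361	162	170	8
nonevents	10-20%	264	246	651	211
nonevents	20-100%	2	10	112	157
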