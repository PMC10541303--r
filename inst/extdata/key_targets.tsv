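uniprot	symbol	degree	relevance_score
P27361	MAPK3	8	9.86
P40763	STAT3	8	9.45
Q16539	MAPK14	8	9.49
P42224	STAT1	8	10.01
P01584	IL1B	7	19.65
P05231	IL6	7	21.34
P01375	TNF	7	29.00
P60568	IL2	7	13.50
P12931	SRC	4	10.84
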