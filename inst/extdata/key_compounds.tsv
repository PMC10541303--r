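peak	name	formula	degree_reported	correlating_targets	rt_min	adduct	calculated_mz_reported	measured_mz	error_ppm_reported	origin
1	Ferulic acid	C10H10O4	3	TNF;IL6;STAT3	4.662	(M+H)+[-H2O]	194.0573	177.0541	3.31	O. koreanum;A. continentalis;P. ginseng;C. aurantium;C. officinale
2	Isoglabrolide	C30H44O4	3	IL1B;MAPK14;STAT3	8.247	(M+H)+	468.324	469.3317	-0.83	G. uralensis
3	Neocnidilide	C12H18O2	3	IL1B;MAPK14;STAT3	8.748	(M+H)+	194.1307	195.1372	4.84	C. officinale
4	Glabric acid	C30H46O5	3	TNF;IL6;MAPK3	8.875	(M+H)+	486.334	487.3424	1.22	G. uralensis
5	Liquiritic acid	C30H46O4	3	TNF;IL6;MAPK3	9.404	(M+H)+[-H2O]	470.3396	453.3367	-1.12	G. uralensis
6	Scopoletin	C10H8O4	4	TNF;IL1B;MAPK14;STAT3	10.887	(M+H)+[-H2O]	192.0414	175.0381	4.49	O. koreanum;A. continentalis;A. decursiva;C. aurantium;C. officinale
7	Erybacin B	C19H18O5	3	TNF;STAT3;MAPK14	15.375	(M+H)+	326.1154	327.1236	-2.09	G. uralensis
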