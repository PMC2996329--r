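strain	type	frequency	sem	bound	bound_value
MH3360	INTERNAL_DELETION	60.6	3.3	FALSE	NA
MH3360	ISOCHROMOSOME	10.8	1.3	FALSE	NA
MH3360	RING	3.2	1.0	FALSE	NA
MH3360	TRANSLOCATION	1.4	0.7	FALSE	NA
MH3360	OTHER	0.4	3.6	FALSE	NA
MH3360	ALLELIC	2.9	4.2	FALSE	NA
MH3360	CHROMOSOME_LOSS	20.7	2.4	FALSE	NA
MH3359	INTERNAL_DELETION	13.4	5.5	FALSE	NA
MH3359	ISOCHROMOSOME	3.2	0.8	FALSE	NA
MH3359	RING	0.3	0.3	FALSE	NA
MH3359	TRANSLOCATION	0.3	0.3	FALSE	NA
MH3359	OTHER	0.3	2.9	FALSE	NA
MH3359	ALLELIC	81.5	6.4	FALSE	NA
MH3359	CHROMOSOME_LOSS	1.0	1.0	FALSE	NA
MH3768	TY_GC	22.1	7.8	FALSE	NA
MH3768	INTRA_TY_DELETION	59.1	8.5	FALSE	NA
MH3768	INTERNAL_DELETION	7.4	5.0	FALSE	NA
MH3768	ISOCHROMOSOME	3.7	0.6	FALSE	NA
MH3768	RING	1.5	0.6	FALSE	NA
MH3768	TRANSLOCATION	0.3	0.3	FALSE	NA
MH3768	OTHER	0	3.9	TRUE	3.9
MH3768	ALLELIC	0	3.9	TRUE	3.9
MH3768	CHROMOSOME_LOSS	5.8	0.2	FALSE	NA
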