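# Published ICE FALCON change coefficients for the genome-wide significant
# handgrip-strength CpGs, both directions.  fwd_* = methylation-to-trait,
# rev_* = trait-to-methylation; *_cotwin_change and *_self_change are the
# marginal-minus-joint coefficient changes; *_ratio is the published
# |co-twin change| / |self change| (printed only where the study reported
# it; NA elsewhere).
row	chrom	symbol	pos	fwd_cotwin_change	fwd_p_cotwin	fwd_self_change	fwd_p_self	fwd_ratio	rev_cotwin_change	rev_p_cotwin	rev_self_change	rev_p_self	rev_ratio
1	chr22	FBLN1	45948590	1.519	2.190e-02	0.044	9.44e-01	34.42	-0.011	1.27e-01	0.008	3.59e-01	NA
2	chr22	FBLN1	45948556	1.539	5.362e-03	0.309	5.49e-01	4.98	-0.011	5.90e-02	0.007	1.92e-01	NA
3	chr9	RXRA	137240415	-2.215	1.210e-13	-0.986	5.76e-06	2.25	0.016	4.98e-02	-0.010	1.63e-01	NA
4	chr9	RXRA	137240420	-2.244	1.300e-14	-0.989	1.24e-06	2.27	0.017	3.86e-01	-0.010	8.26e-01	1.61
5	chr22	FBLN1	45948659	1.348	1.343e-03	0.018	9.60e-01	73.84	-0.016	9.04e-02	0.011	2.78e-01	NA
6	chr9	RXRA	137240405	-2.025	1.880e-09	-0.864	1.53e-03	2.34	0.015	1.60e-01	-0.009	6.29e-01	NA
7	chr3	ABHD14B	52007565	0.191	6.700e-06	0.106	6.12e-03	1.80	-0.101	1.28e-01	0.037	3.68e-01	NA
8	chr9	RXRA	137240398	-1.827	5.350e-06	-0.730	3.59e-02	2.50	0.014	2.85e-02	-0.007	1.24e-01	NA
9	chr22	FBLN1	45948675	1.628	1.290e-19	0.629	4.53e-07	2.59	-0.023	1.87e-01	0.014	5.96e-01	1.62
10	chr3	ABHD14B	52007520	0.176	1.370e-04	0.087	4.34e-02	2.02	-0.099	9.60e-02	0.042	3.90e-01	NA
11	chr9	NA	140117008	0.263	4.720e-14	0.141	1.07e-07	1.86	-0.102	2.50e-01	0.056	6.52e-01	NA
12	chr2	MFSD6	191295760	0.200	4.859e-02	0.070	4.83e-01	2.87	-0.090	1.98e-01	0.038	3.99e-01	NA
13	chr15	NA	91369952	-0.180	1.060e-10	0.017	4.73e-01	10.42	0.090	3.75e-01	-0.079	6.97e-01	NA
14	chr7	TYW1B	72285112	-0.208	1.960e-08	-0.057	6.07e-02	3.66	0.100	5.23e-01	-0.078	8.68e-01	NA
15	chr3	ABHD14B	52007573	0.132	1.428e-02	0.057	2.71e-01	2.31	-0.063	2.84e-01	0.028	7.30e-01	NA
16	chr7	TYW1B	72285120	-0.210	1.050e-08	-0.059	4.58e-02	3.56	0.100	4.41e-01	-0.077	7.08e-01	NA
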