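genotype	count_r0	count_sel4	enrich_sel4	count_sel8	enrich_sel8	count_sel20	enrich_sel20
L-403-P; R-406-S	1	102137	12.42	43	4.50	10	3.21
L-403-A; D-404-K	1	78143	12.15	7	2.69	3	2.00
L-403-A; D-404-A	1	51782	11.74	25	3.96	2	1.60
L-403-V; D-404-S	2	85927	11.55	11	2.44	7	2.16
L-403-H	2	53781	11.09	18	2.94	7	2.16
R-406-K	1	25461	11.03	8	2.82	75	5.22
L-403-F	16	73651	9.32	241875	10.36	25	1.35
L-403-T	25	44223	8.36	414115	10.45	12	0.17
WT	2584	51615	3.88	2391	0.66	510249	6.19
Y-409-S	14	95	2.80	8	0.18	1213	5.37
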