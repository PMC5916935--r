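sample_id	sample_type	age	psa_ng_ml	percent_g4_5	total_cancer_volume_cc	gleason
PCa_1	PCa	56	10.20	70	4.37	4+3=7
PCa_2	PCa	66	3.92	90	8.55	4+3=7
PCa_3	PCa	50	15.48	80	9.00	4+3=7
PCa_4	PCa	58	6.36	60	9.03	4+3=7
PCa_5	PCa	60	21.30	90	4.93	4+3=7
PCa_6	PCa	70	3.27	70	6.00	4+3=7
PCa_7	PCa	46	30.13	90	1.00	4+3=7
PCa_8	PCa	68	16.11	95	29.39	4+3=7
PCa_9	PCa	64	13.40	60	7.20	4+3=7
PCa_10	PCa	56	8.71	50	4.56	4+3=7
BPH_1	BPH	62	3.14	NA	NA	NA
BPH_2	BPH	73	4.20	NA	NA	NA
BPH_3	BPH	69	11.16	NA	NA	NA
BPH_4	BPH	71	13.80	NA	NA	NA
BPH_5	BPH	56	7.67	NA	NA	NA
BPH_6	BPH	44	3.42	NA	NA	NA
BPH_7	BPH	61	8.21	NA	NA	NA
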