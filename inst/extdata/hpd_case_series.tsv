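patient_id	line	ttf_months	tgk_ratio	tgr_ratio	tbi_pct
31	second	1.8	7.91	6.2	593.667
29	first	1.6	NA	NA	579.527
25	first	1.9	NA	NA	35.1115
23	first	1.9	NA	NA	9.41931
26	first	1.3	NA	NA	53.4903
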