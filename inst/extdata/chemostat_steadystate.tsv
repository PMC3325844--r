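condition	D_per_h	cdw_g_per_l	cdw_sd	pha_pct_cdw	pha_sd	resid_C_g_per_l	resid_N_g_per_l	molpct_C6	molpct_C8	molpct_C10
carbon	0.1	1.46	0.04	25.78	0.97	ND	0.112	3.3	53.4	43.3
dual	0.1	4.35	0.13	61.94	4.95	ND	ND	4.8	42.8	52.4
nitrogen	0.1	4.63	0.14	80.58	0.24	1.53	ND	4.3	40.2	55.5
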