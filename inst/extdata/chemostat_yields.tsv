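condition	y_xc	y_xn	c0_n0	border
carbon	1.11	9.8	5.83	10.4
dual	1.16	16.67	16.56	NA
nitrogen	1.01	17.74	26.97	20.5
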