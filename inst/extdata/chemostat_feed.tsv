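condition	decanoate_g_per_l	nh4cl_g_per_l
carbon	1.8775	1
dual	5.333	1
nitrogen	8.6855	1
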