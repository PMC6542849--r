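name	z	d_dehydrated_nm	a0_nm	b_per_M	mu_m2_per_Vs	D_nm2_per_ns
Li	1	0.152	0.38	0.2	4.01e-08	1.03
Na	1	0.234	0.36	0.06	5.19e-08	1.33
K	1	0.298	0.33	0.01	7.62e-08	1.96
Cs	1	0.334	0.33	0.01	8.01e-08	2.06
Mg	2	0.144	0.43	0.21	5.49e-08	0.706
Cl	-1	0.362	0.30	0	7.91e-08	2.03
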