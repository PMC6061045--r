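mouse_gene	r	direction	p_mouse	human_gene	p_human	n_animals
Lbh	-0.6941	Down	0.000042	LBH	0.046239	28
St6galnac4	0.5970	Up	0.000797	ST6GALNAC4	0.011877	28
Arsj	0.6609	Up	0.000129	ARSJ	0.045099	28
AW549877	-0.6009	Down	0.000722	C5orf51	0.019214	28
Shf	-0.6455	Down	0.000208	SHF	0.044829	28
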