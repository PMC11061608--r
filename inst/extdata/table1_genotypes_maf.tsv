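sample	gene	variant_classification	protein_change
DMS114	TP53	Nonsense_Mutation	p.R306*
DMS114	SMARCA4	Nonsense_Mutation	p.E706*
SBC5	TP53	Missense_Mutation	p.R273H
SBC5	SMARCA4	Nonsense_Mutation	p.Q184*
H841	TP53	Missense_Mutation	p.P151S
H841	SMARCA4	Nonsense_Mutation	p.R1077*
H2286	TP53	Nonsense_Mutation	p.R342*
H2286	SMARCA4	Missense_Mutation	p.T910M
H157DM	TP53	Nonsense_Mutation	p.E204*
H157DM	SMARCA4	Frame_Shift_Del	p.N728fs
H196	TP53	Missense_Mutation	p.C176F
H196	RB1	Nonsense_Mutation	p.R579*
SW1271	TP53	Missense_Mutation	p.E285K
SW1271	SMARCA4	Missense_Mutation	p.G1232S
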