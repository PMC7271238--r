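gene_a	gene_b	combined
AKT1	SOD1	0.925
AKT1	VCP	0.727
MAPK3	SQSTM1	0.623
MTOR	SQSTM1	0.573
RPS6	HNRNPA1	0.591
RPS6	UBQLN2	0.453
RPS6KB1	SQSTM1	0.573
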