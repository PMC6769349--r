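# Published per-pair Ka, Ks, Ka/Ks and duplication dates (Mya) for the 10
# moso bamboo GRF paralog pairs (lambda = 6.5e-9 subs/site/year).
id_a	id_b	ka	ks	ratio	t_mya
PeGRF9	PeGRF6	0.04615	0.15242	0.303	11.72461538
PeGRF8	PeGRF13	0.03147	0.14266	0.221	10.97384615
PeGRF7	PeGRF15	0.3019	0.47649	0.634	36.65307692
PeGRF7	PeGRF11	0.07237	0.391	0.185	30.07692308
PeGRF5	PeGRF14	0.18311	0.25592	0.716	19.68615385
PeGRF4	PeGRF5	0.21185	0.4148	0.511	31.90769231
PeGRF4	PeGRF14	0.31207	0.4686	0.666	36.04615385
PeGRF3	PeGRF2	0.04093	0.09334	0.438	7.18
PeGRF17	PeGRF16	0.03841	0.14145	0.272	10.88076923
PeGRF11	PeGRF15	0.01046	0.12157	0.086	9.351538462
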