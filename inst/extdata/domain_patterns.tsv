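# Conserved-domain spacing patterns for GRF family scanning.
# One row per pattern element, in order. 'residues' is the allowed residue
# class at the element position; 'min_gap'/'max_gap' bound the number of
# arbitrary residues between this element and the next (ignored on the last
# element). 'max_mismatch' is the per-pattern substitution budget shared by
# all elements (listed on every row for readability).
# QLQ: Q-x(2,4)-L-x(2,4)-Q protein-interaction core.
# WRC: W-R-C...C...C...H, the Trp-Arg-Cys region whose Cys3His spacing forms
#      the zinc finger (the C of WRC is the first finger cysteine).
# FFD / TQL: short C-terminal tripeptides, one substitution tolerated.
name	element	residues	min_gap	max_gap	max_mismatch
QLQ	1	Q	2	4	0
QLQ	2	L	2	4	0
QLQ	3	Q	0	0	0
WRC	1	W	0	0	0
WRC	2	R	0	0	0
WRC	3	C	6	12	0
WRC	4	C	8	14	0
WRC	5	C	1	3	0
WRC	6	H	0	0	0
FFD	1	F	0	0	1
FFD	2	F	0	0	1
FFD	3	D	0	0	1
TQL	1	T	0	0	1
TQL	2	Q	0	0	1
TQL	3	L	0	0	1
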