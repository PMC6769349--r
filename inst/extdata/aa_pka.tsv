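# pKa values for the ionizable groups used in the isoelectric-point model
# (EMBOSS set). 'sign' is +1 for basic groups (protonated form charged) and
# -1 for acidic groups (deprotonated form charged). NTERM/CTERM are the
# peptide termini, counted once per chain.
group	pka	sign
NTERM	8.6	1
CTERM	3.6	-1
C	8.5	-1
D	3.9	-1
E	4.1	-1
H	6.5	1
K	10.8	1
R	12.5	1
Y	10.1	-1
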