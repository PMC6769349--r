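# Curated cis-regulatory element dictionary (IUPAC consensus strings from
# the plant promoter literature). Categories: development / hormone /
# stress; subcategory names the response. Patterns are matched on the
# forward strand of the supplied promoter; CGTCA and TGACG are reverse
# complements of one another but are kept as separate entries because
# MeJA-response censuses conventionally report them separately.
name	iupac	category	subcategory
Skn-1_motif	GTCAT	development	endosperm
GCN4_motif	TGAGTCA	development	endosperm
CAT-box	GCCACT	development	meristem
CCGTCC-box	CCGTCC	development	meristem
circadian	CAANNNNATC	development	circadian
CGTCA-motif	CGTCA	hormone	MeJA
TGACG-motif	TGACG	hormone	MeJA
GARE-motif	TCTGTTG	hormone	GA
P-box	CCTTTTG	hormone	GA
ABRE	ACGTG	hormone	ABA
motif_IIb	CCGCCGCGCT	hormone	ABA
CE1	TGCCACCGG	hormone	ABA
TCA-element	CCATCTTTTT	hormone	SA
TGA-element	AACGAC	hormone	auxin
AuxRR-core	GGTCCAT	hormone	auxin
TGA-box	TGACGTAA	hormone	auxin
HSE	AAAAAATTTC	stress	heat
ARE	AAACCA	stress	low-temperature
GC-motif	CCCCCG	stress	low-temperature
LTR	CCGAAA	stress	low-temperature
Box-W1	TTGACC	stress	fungal-elicitor
WUN-motif	AAATTTCCT	stress	wound
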