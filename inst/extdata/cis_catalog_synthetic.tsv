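element_id	motif	category
ABRE	TACGTGGC	ABA response
ABRE3a	GCAACGTGTC	ABA response
CARE	CATGCCGT	GA response
GARE-motif	TCTGTTGACA	GA response
P-box	CCTTTTGAGT	GA response
ERE	ATTTCAAATC	ETH response
TCA-element	CCATCTTTTT	SA response
SARE	TTCGACCATC	SA response
CGTCA-motif	CGTCAAGTGG	JA response
TGACG-motif	TGACGTAAGG	JA response
W box	TTGACCTA	wounding and pathogen response
WUN-motif	AAATTTCCTG	wounding and pathogen response
box S	AGCCACCAAC	wounding and pathogen response
LTR	CCGAAATC	cold response
MBS	CAACTGGC	drought response
MYC	CATTTGCAYC	drought response
STRE	AGGGGCGG	heat and osmotic stress response
ARE	AAACCAWT	anoxic response
GC-motif	CCCCCGGG	anoxic response
TC-rich repeats	ATTTTCTTCA	defense and stress response
G-Box	CACGTTGG	light response
Box 4	ATTAATGG	light response
AP-1	TGAGTCAY	Cd response
circadian	CAAGNNTATC	circadian response
MSA-like	TCCAACGG	cell cycle response
E2Fb	GCGGGAAA	cell cycle response
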