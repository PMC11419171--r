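dataset	group	afr	eur
AOU	cases	542	1584
AOU	controls	31435	76664
eMERGE	cases	353	1890
eMERGE	controls	9934	39623
PMBB	cases	562	636
PMBB	controls	6524	12969
UKBB	cases	112	4429
UKBB	controls	4524	252759
BioVU	cases	260	837
BioVU	controls	6376	26599
META	cases	2079	10271
META	controls	58543	407718
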