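gene	variant_class	observed	expected
DHCR7	plof	0	100
TSFM	plof	1	29.2
CCDC59	plof	0	21.6
ATP5PB	plof	0	15.8
MTG2	plof	0	13.4
BRF2	plof	0	11.1
GTF2H3	plof	0	10.7
CENPF	plof	0	10.5
PUM3	plof	0	10.2
ELOF1	plof	0	10.2
PKHD1	plof	0	9.62
RPAP2	plof	0	9.26
WARS2	plof	0	9.10
PNKP	plof	0	8.53
BRIP1	plof	0	7.74
GBE1	plof	0	7.29
AGK	plof	0	5.79
CDC7	plof	0	5.34
DIAPH3	plof	0	5.29
MRPS30	moderate	1	48.2
PMM2	moderate	4	54.1
HYLS1	moderate	1	14.9
MVD	moderate	0	11.1
GLE1	moderate	0	11.0
CASP9	moderate	1	11.9
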