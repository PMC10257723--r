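set	bin	deficit_in_set	no_deficit_in_set	deficit_not_in_set	no_deficit_not_in_set
ar_omim	[1,5)	39	103	60	623
ar_omim	[5,Inf)	9	147	10	1074
cellline_essential	[1,5)	31	30	61	603
cellline_essential	[5,Inf)	11	85	8	942
mouse_lethal	[1,5)	40	104	30	341
mouse_lethal	[5,Inf)	13	179	2	539
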