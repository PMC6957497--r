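marker	chrom	cM
rs01	22	0.0
rs02	22	0.4
rs03	22	0.8
rs04	22	1.2
rs05	22	1.6
rs06	22	2.0
rs07	22	2.4
rs08	22	2.8
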