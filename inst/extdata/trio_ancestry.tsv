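marker	F	M	C
rs01	1	2	2
rs02	1	2	2
rs03	1	2	2
rs04	0	2	2
rs05	1	2	2
rs06	1	2	2
rs07	1	2	2
rs08	1	2	2
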