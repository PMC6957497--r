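marker	F	M	C
rs01	0.99	0.98	0.99
rs02	0.99	0.97	0.99
rs03	0.98	0.99	0.99
rs04	0.95	0.99	0.96
rs05	0.99	0.99	0.99
rs06	0.99	0.72	0.99
rs07	0.99	0.98	0.99
rs08	0.99	0.99	0.99
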