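trio F 0 0 1 -9
trio M 0 0 2 -9
trio C F M 1 -9
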