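species,A1,A2,A3
P1,1,1,0
P2,1,0,0
P3,1,1,1
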