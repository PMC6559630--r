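species,level,origin
P1,plant,native
P2,plant,native
P3,plant,native
A1,animal,nonnative
A2,animal,native
A3,animal,native
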