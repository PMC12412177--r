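name,mz,charge,ccs,adduct
d7-PC (15:0-18:1) [M+H]+,753.6,1,292.8,[M+H]+
d7-LysoPC (18:1) [M+H]+,529.4,1,236.0,[M+H]+
d7-PE (15:0-18:1) [M+H]+,711.6,1,280.1,[M+H]+
d7-LysoPE (18:1) [M+H]+,487.3,1,218.9,[M+H]+
d7-LysoPE (18:1) [M+Na]+,509.3,1,225.1,[M+Na]+
d7-LysoPC (18:1) [M+Na]+,551.4,1,238.6,[M+Na]+
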