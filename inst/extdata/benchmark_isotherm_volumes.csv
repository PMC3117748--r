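level_C,volume_cc
43,1.38
45,1.10
50,0.99
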