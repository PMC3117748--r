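rat,mri_cc,histology_cc
1,0.953,0.945
2,0.970,0.950
3,0.987,0.923
4,0.946,0.990
5,0.933,0.923
6,0.967,0.941
7,0.978,0.992
8,0.989,0.988
9,0.958,0.967
10,1.121,1.125
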