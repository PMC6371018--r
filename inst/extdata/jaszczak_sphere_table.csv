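sphere,diameter_mm,activity_MBq
S1,34,11.10
S2,31,8.88
S3,25,4.44
S4,16,1.11
S6,12,0.56
S7,10,0.28
S8,8,0.14
S9,2,0
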