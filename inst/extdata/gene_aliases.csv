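alias,symbol
KI-67,MKI67
Ki-67,MKI67
TCAB1,WRAP53
PD-L1,CD274
B7-H4,VTCN1
CXCL8,CXCL8
IL-6,IL6
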