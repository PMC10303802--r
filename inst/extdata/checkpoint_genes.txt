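VTCN1
CD274
CTLA4
TIGIT
PDCD1
BTLA
LAG3
EDNRB
HAVCR2
SLAMF1
PDCD1LG2
CD276
IDO1
CD47
SIRPA
CD27
CD40
ICOS
TNFRSF9
TNFRSF18
KIR2DL1
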