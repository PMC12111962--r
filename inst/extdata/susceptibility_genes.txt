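# Cancer susceptibility gene list used by the packaged germline examples.
TP53
SERPINA1
CDKN2A
RAD50
MUTYH
BRCA1
BRCA2
ATM
CHEK2
PALB2
MLH1
MSH2
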