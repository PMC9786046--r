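ABCA1
ABCG1
ABCG5
ABCG8
ANGPTL4
APOA1
APOA4
APOB
APOC2
APOE
APOH
CD36
CETP
CYP27A1
CYP39A1
CYP46A1
CYP7A1
LCAT
LDLR
LDLRAP1
LIPA
LIPC
LIPG
LPA
LPL
LRP1
LRP2
LRPAP1
MYLIP
NPC1
NPC1L1
NPC2
PCSK9
PLTP
SCARB1
SOAT1
SORT1
STAR
STARD3
TSPO
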