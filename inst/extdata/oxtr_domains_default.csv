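label,start,end
N-term,1,38
TM1,39,64
ICL1,65,74
TM2,75,99
ECL1,100,110
TM3,111,134
ICL2,135,153
TM4,154,175
ECL2,176,199
TM5,200,226
ICL3,227,267
TM6,268,290
ECL3,291,301
TM7,302,327
C-term,328,389
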