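group,residue,pKa
sidechain_pos,K,10.8
sidechain_pos,R,12.5
sidechain_pos,H,6.5
sidechain_neg,D,3.9
sidechain_neg,E,4.1
sidechain_neg,C,8.5
sidechain_neg,Y,10.1
nterm,*,8.6
cterm,*,3.6
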