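group,residue,pKa
sidechain_pos,K,10.0
sidechain_pos,R,12.0
sidechain_pos,H,5.98
sidechain_neg,D,4.05
sidechain_neg,E,4.45
sidechain_neg,C,9.0
sidechain_neg,Y,10.0
nterm,*,7.5
nterm,A,7.59
nterm,M,7.0
nterm,S,6.93
nterm,P,8.36
nterm,T,6.82
nterm,V,7.44
nterm,E,7.7
cterm,*,3.55
cterm,D,4.55
cterm,E,4.75
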