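aa,polarity,charge,volume_class,volume_A3
A,nonpolar,neutral,1,88.6
R,polar,positive,5,173.4
N,polar,neutral,2,114.1
D,polar,negative,2,111.1
C,polar,neutral,2,108.5
Q,polar,neutral,3,143.8
E,polar,negative,3,138.4
G,nonpolar,neutral,1,60.1
H,polar,positive,4,153.2
I,nonpolar,neutral,4,166.7
L,nonpolar,neutral,4,166.7
K,polar,positive,4,168.6
M,nonpolar,neutral,4,162.9
F,nonpolar,neutral,5,189.9
P,nonpolar,neutral,2,112.7
S,polar,neutral,1,89.0
T,polar,neutral,2,116.1
W,nonpolar,neutral,5,227.8
Y,polar,neutral,5,193.6
V,nonpolar,neutral,3,140.0
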