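taxon,state
Callithrix,monogamous
Cebuella,monogamous
Mico,monogamous
Leontopithecus,monogamous
Saguinus,monogamous
Callimico,monogamous
Cebus,non-monogamous
Saimiri,non-monogamous
Aotus,monogamous
Alouatta,non-monogamous
Ateles,non-monogamous
Lagothrix,non-monogamous
Brachyteles,non-monogamous
Pithecia,monogamous
Chiropotes,non-monogamous
Cacajao,non-monogamous
Callicebus,monogamous
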