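>Callithrix_jacchus Cebidae, Pro8 ligand (synthetic stand-in)
TGTTATATTCAGAATTGTCCTCCTGGT
>Callithrix_geoffroyi Cebidae, Pro8 ligand (synthetic stand-in)
TGTTATATTCAGAATTGTCCTCCTGGT
>Cebuella_pygmaea Cebidae, Pro8 ligand (synthetic stand-in)
TGTTATATTCAGAATTGTCCTCCTGGT
>Mico_argentatus Cebidae, Pro8 ligand (synthetic stand-in)
TGTTATATTCAGAATTGTCCTCCTGGT
>Leontopithecus_rosalia Cebidae, Pro8 ligand (synthetic stand-in)
TGTTATATTCAGAATTGTCCTCCTGGT
>Saguinus_oedipus Cebidae, Pro8 ligand (synthetic stand-in)
TGTTATATTCAGAATTGTCCTCCTGGT
>Saguinus_mystax Cebidae, Pro8 ligand (synthetic stand-in)
TGTTATATTCAGAATTGTCCTCCTGGT
>Callimico_goeldii Cebidae, Pro8 ligand (synthetic stand-in)
TGTTATATTCAGAATTGTCCTCCTGGT
>Cebus_apella Cebidae, Pro8 ligand (synthetic stand-in)
TGTTATATTCAGAATTGTCCTCCTGGT
>Cebus_albifrons Cebidae, Pro8 ligand (synthetic stand-in)
TGTTATATTCAGAATTGTCCTCCTGGT
>Saimiri_sciureus Cebidae, Pro8 ligand (synthetic stand-in)
TGTTATATTCAGAATTGTCCTCCTGGT
>Aotus_nancymaae Cebidae, Pro8 ligand (synthetic stand-in)
TGTTATATTCAGAATTGTCCTCCTGGT
>Alouatta_caraya Atelidae, Leu8 ligand (synthetic stand-in)
TGTTATATTCAGAATTGTCCTCTTGGT
>Alouatta_seniculus Atelidae, Leu8 ligand (synthetic stand-in)
TGTTATATTCAGAATTGTCCTCTTGGT
>Ateles_geoffroyi Atelidae, Pro8 ligand (synthetic stand-in)
TGTTATATTCAGAATTGTCCTCCTGGT
>Lagothrix_lagotricha Atelidae, Phe2 ligand (synthetic stand-in)
TGTTTTATTCAGAATTGTCCTCTTGGT
>Brachyteles_arachnoides Atelidae, Leu8 ligand, synonymous codon (synthetic stand-in)
TGTTATATTCAGAATTGTCCTCTGGGT
>Pithecia_pithecia Pitheciidae, Leu8 ligand (synthetic stand-in)
TGTTATATTCAGAATTGTCCTCTTGGT
>Pithecia_irrorata Pitheciidae, Leu8 ligand (synthetic stand-in)
TGTTATATTCAGAATTGTCCTCTTGGT
>Chiropotes_satanas Pitheciidae, Thr8 ligand (synthetic stand-in)
TGTTATATTCAGAATTGTCCTACTGGT
>Cacajao_calvus Pitheciidae, Leu8 ligand (synthetic stand-in)
TGTTATATTCAGAATTGTCCTCTTGGT
>Callicebus_moloch Pitheciidae, Ala8 ligand (synthetic stand-in)
TGTTATATTCAGAATTGTCCTGCTGGT
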