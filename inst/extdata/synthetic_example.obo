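format-version: 1.2
remark: synthetic miniature ontology for examples and tests; not a GO release

[Term]
id: GO:0000001
name: biological process root

[Term]
id: GO:0000010
name: macromolecule catabolic process
is_a: GO:0000001 ! biological process root

[Term]
id: GO:0000011
name: mRNA catabolic process
is_a: GO:0000010 ! macromolecule catabolic process

[Term]
id: GO:0000012
name: protein catabolic process
is_a: GO:0000010 ! macromolecule catabolic process

[Term]
id: GO:0000020
name: transport
is_a: GO:0000001 ! biological process root

[Term]
id: GO:0000021
name: protein targeting
is_a: GO:0000020 ! transport
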