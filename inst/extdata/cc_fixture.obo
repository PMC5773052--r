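format-version: 1.2
ontology: locrex-cc-fixture
remark: Synthetic subset of GO Cellular Component for tests and examples.

[Term]
id: GO:0005575
name: cellular_component

[Term]
id: GO:0043226
name: organelle
is_a: GO:0005575

[Term]
id: GO:0043227
name: membrane-bounded organelle
is_a: GO:0043226

[Term]
id: GO:0016020
name: membrane
is_a: GO:0005575

[Term]
id: GO:0005576
name: extracellular region
is_a: GO:0005575

[Term]
id: GO:0032991
name: protein-containing complex
is_a: GO:0005575

[Term]
id: GO:0005737
name: cytoplasm
is_a: GO:0005575

[Term]
id: GO:0005829
name: cytosol
relationship: part_of GO:0005737

[Term]
id: GO:0005634
name: nucleus
is_a: GO:0043227

[Term]
id: GO:0005730
name: nucleolus
is_a: GO:0043226
relationship: part_of GO:0005634

[Term]
id: GO:0005739
name: mitochondrion
is_a: GO:0043227

[Term]
id: GO:0005759
name: mitochondrial matrix
relationship: part_of GO:0005739

[Term]
id: GO:0005773
name: vacuole
is_a: GO:0043227

[Term]
id: GO:0000323
name: lytic vacuole
is_a: GO:0005773

[Term]
id: GO:0005774
name: vacuolar membrane
is_a: GO:0016020
relationship: part_of GO:0005773

[Term]
id: GO:0009705
name: plant-type vacuole membrane
is_a: GO:0005774

[Term]
id: GO:0005886
name: plasma membrane
is_a: GO:0016020

[Term]
id: GO:0016328
name: lateral plasma membrane
relationship: part_of GO:0005886

[Term]
id: GO:0005783
name: endoplasmic reticulum
is_a: GO:0043227

[Term]
id: GO:0005794
name: Golgi apparatus
is_a: GO:0043227

[Term]
id: GO:0005777
name: peroxisome
is_a: GO:0043227

[Term]
id: GO:0009507
name: chloroplast
is_a: GO:0043227

[Term]
id: GO:0009707
name: chloroplast outer membrane
is_a: GO:0016020
relationship: part_of GO:0009507

[Term]
id: GO:0000502
name: proteasome complex
is_a: GO:0032991

[Term]
id: GO:0005839
name: proteasome core complex
is_a: GO:0000502

[Term]
id: GO:0008372
name: cellular component unknown
is_obsolete: true
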