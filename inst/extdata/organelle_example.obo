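format-version: 1.2
ontology: organelle-example

[Term]
id: CC:0000
name: cellular_component
namespace: cellular_component

[Term]
id: CC:0001
name: organelle
namespace: cellular_component
is_a: CC:0000 ! cellular_component

[Term]
id: CC:0002
name: membrane-bound organelle
namespace: cellular_component
is_a: CC:0001 ! organelle

[Term]
id: CC:0003
name: intracellular organelle
namespace: cellular_component
alt_id: CC:9003
is_a: CC:0001 ! organelle

[Term]
id: CC:0004
name: intracellular membrane-bound organelle
namespace: cellular_component
is_a: CC:0002 ! membrane-bound organelle
is_a: CC:0003 ! intracellular organelle

[Term]
id: CC:0005
name: organelle envelope
namespace: cellular_component
relationship: part_of CC:0002 ! membrane-bound organelle
relationship: part_of CC:0003 ! intracellular organelle

[Term]
id: CC:0006
name: outdated organelle term
namespace: cellular_component
is_a: CC:0001 ! organelle
is_obsolete: true
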