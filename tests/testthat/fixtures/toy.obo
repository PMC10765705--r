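format-version: 1.2
ontology: toy

[Term]
id: HP:0000001
name: All

[Term]
id: HP:0000002
name: left branch
is_a: HP:0000001 ! All

[Term]
id: HP:0000003
name: right branch
alt_id: HP:0000099
is_a: HP:0000001 ! All
relationship: part_of HP:0000001

[Term]
id: HP:0000004
name: shared leaf
is_a: HP:0000002 ! left branch
is_a: HP:0000003 ! right branch

[Term]
id: HP:0000005
name: gone
is_obsolete: true
replaced_by: HP:0000002

[Typedef]
id: part_of
name: part of
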