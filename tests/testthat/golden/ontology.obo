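format-version: 1.2
ontology: toy

[Term]
id: TOY:0000001
name: bepod
namespace: toy_process

[Term]
id: TOY:0000002
name: nomak giradas
namespace: toy_process
is_a: TOY:0000001

[Term]
id: TOY:0000003
name: voket feriben
namespace: toy_process
relationship: part_of TOY:0000002

[Term]
id: TOY:0000004
name: loduvod dafuned
namespace: toy_process
relationship: part_of TOY:0000002
relationship: part_of TOY:0000003

[Term]
id: TOY:0000005
name: dugefer kobubep
namespace: toy_process
is_a: TOY:0000003
relationship: part_of TOY:0000002

[Term]
id: TOY:0000006
name: gipusut
namespace: toy_process
is_a: TOY:0000003

[Term]
id: TOY:0000007
name: ketelad zunop
namespace: toy_process
is_a: TOY:0000006

[Term]
id: TOY:0000008
name: riduk fulatop
namespace: toy_process
is_a: TOY:0000004
is_a: TOY:0000001

[Term]
id: TOY:0000009
name: zasen
namespace: toy_process
is_a: TOY:0000004
is_a: TOY:0000001

[Term]
id: TOY:0000010
name: lubup
namespace: toy_process
is_a: TOY:0000009

[Term]
id: TOY:0000011
name: resarip
namespace: toy_process
is_a: TOY:0000007
is_a: TOY:0000005

[Term]
id: TOY:0000012
name: fibub
namespace: toy_process
relationship: part_of TOY:0000005
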