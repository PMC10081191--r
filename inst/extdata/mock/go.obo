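format-version: 1.2
ontology: go-mini

[Term]
id: GO:0008152
name: metabolic process
namespace: biological_process

[Term]
id: GO:1000001
name: mock process 1
namespace: biological_process
alt_id: GO:0200001
is_a: GO:0008152 ! parent

[Term]
id: GO:1000002
name: mock process 2
namespace: biological_process
is_a: GO:0008152 ! parent

[Term]
id: GO:1000003
name: mock process 3
namespace: biological_process
is_a: GO:1000001 ! parent
is_a: GO:1000002 ! parent

[Term]
id: GO:1000004
name: mock process 4
namespace: biological_process
is_a: GO:1000003 ! parent

[Term]
id: GO:1000005
name: mock process 5
namespace: biological_process
is_a: GO:1000003 ! parent

[Term]
id: GO:0900001
name: obsolete mock process
namespace: biological_process
is_obsolete: true

[Term]
id: GO:0990001
name: non-metabolic mock process
namespace: biological_process

[Typedef]
id: part_of
name: part of
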